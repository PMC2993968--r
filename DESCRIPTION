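Package: delayseq
Title: Integrative miRNA and mRNA Sequencing Analysis of Delayed
    Implantation Versus Estrogen Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable, tested reimplementation of the computational
    pipeline used to compare small-RNA and SAGE/DGE (digital gene
    expression) sequencing libraries from mouse uterus under delayed
    implantation and estrogen-induced activation. Provides 3' adapter
    trimming by the 8-nt perfect-match rule, read collapsing, nine-way
    small-RNA classification against a genome annotation, tags-per-million
    normalisation with the Kal et al. two-proportion z-test and Bonferroni
    correction, isomiR and miRNA-editing detection via Needleman-Wunsch
    global alignment with a per-position median-centred Z-score test,
    DpnII 16-bp tag extraction with reliability-scored tag-to-gene mapping,
    and miRNA-mRNA integration (host-gene correlation, coherent targets,
    target-direction enrichment). A synthetic-data module generates every
    input with planted ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
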