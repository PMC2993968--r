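# delayseq

Integrative analysis of miRNA and mRNA sequencing from mouse uterus under
delayed implantation and estrogen activation.

Delayed implantation arrests the mouse uterus and blastocyst at a
pre-implantation state; estrogen releases the arrest ("activation").
Comparing one small-RNA library and one SAGE-style digital gene expression
(DGE) library per condition raises a chain of small but easy-to-get-wrong
computational problems, and `delayseq` implements that chain as tested,
pipeable R functions:

* **3' adapter trimming** by the 3'-most perfect match to the first 8 nt of
  the adapter, 18–30 nt size selection, and collapsing to unique tags with
  per-library counts;
* **nine-way classification** (miRNA, piRNA, tRNA, rRNA, snRNA, snoRNA,
  mRNA, genomic, unknown) by exact genome matching with a fixed category
  priority;
* **differential expression** by the pooled two-proportion z-test of
  Kal et al. on raw counts,

  z = (p̂₁ − p̂₂) / √( p̂₀(1 − p̂₀)(1/N₁ + 1/N₂) ),   p̂₀ = (n₁+n₂)/(N₁+N₂),

  with TPM normalisation, Bonferroni correction and signed fold changes in
  the reciprocal-negative convention (−2.00 means halved);
* **isomiR/editing detection**: Needleman–Wunsch global alignment of reads
  to mature miRNAs (match +1, mismatch −1, gap open −2, gap extend −1),
  per-position editing rates, and the median-centred Z-score test
  (significant editing at p ≤ 0.01, upper tail);
* **DGE tag analysis**: 16-bp tag extraction 3' of the 3'-most DpnII site
  (GATC), reliability-scored tag-to-UniGene-cluster mapping
  (score = #mRNA + #HTS-mRNA + 0.5·#EST-poly(A), top-2 clusters kept),
  (0,1)/(1,0) singleton removal, match-class summaries;
* **integration**: miRNA/host-gene correlation on log10(TPM+1), coherent
  (opposite-direction) target classification, and chi-square enrichment of
  predicted-target directions;
* a **synthetic-data module** that generates every input with planted
  ground truth (category mix, fold changes, editing positions, DpnII tags,
  coherent targets), so the whole pipeline is testable offline.

Results come back as tibbles with `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` views.

## Worked example

```r
library(delayseq)

cfg <- pipeline_config(
  seed = 7,
  sim  = smallrna_sim_config(n_reads_per_library = 2e4)
)
bundle <- run_pipeline(cfg)

bundle$mirna_de_significant[, c("feature", "tpm_delay", "tpm_activation",
                                "signed_fold", "p_bonferroni")]
#> # A tibble: 7 × 5
#>   feature      tpm_delay tpm_activation signed_fold p_bonferroni
#>   <chr>            <dbl>          <dbl>       <dbl>        <dbl>
#> 1 mmu-let-7b      146500         112950       -1.30     1.77e-22
#> 2 mmu-let-7f       96900         126000        1.30     2.30e-19
#> 3 mmu-miR-145       4100           1600       -2.56     2.74e- 5
#> 4 mmu-miR-146b      8500          27550        3.24     1.67e-45
#> 5 mmu-miR-16        9500           3700       -2.57     7.89e-12
#> 6 mmu-miR-21       24450          33050        1.35     2.65e- 6
#> 7 mmu-miR-29a      30950          22050       -1.40     3.01e- 7
```

The simulator planted activation/delay folds on these miRNAs (among them
miR-146b at 3.52 and miR-21 at 1.44); the screen (TPM > 100 in either
library, |fold| > 1.2, Bonferroni p < 0.001) recovers exactly the planted
set with no false calls among the null miRNAs. Realised folds track the
planted values tightly for abundant miRNAs and within count noise for the
rare ones (miR-16 and miR-145 sit near 200 reads here).

Editing was planted at seed-region positions 4 and 5 of let-7a, at a higher
per-read rate under delay (0.08) than activation (0.02):

```r
glance(bundle$editing_profiles[["mmu-let-7a.delay"]])
#> # A tibble: 1 × 6
#>   mirna      library n_positions total_coverage n_significant significant_positions
#>   <chr>      <chr>         <int>          <dbl>         <int> <chr>
#> 1 mmu-let-7a delay            22           3225             2 4,5

bundle$seed_region_comparison
#> # A tibble: 1 × 6
#>   edited_a coverage_a edited_b coverage_b     z        p
#>      <dbl>      <dbl>    <dbl>      <dbl> <dbl>    <dbl>
#> 1      536       6450      122       6442  16.6 1.56e-61
```

Only positions 4 and 5 are flagged (p ≤ 0.01, median-centred Z), and the
delay-versus-activation seed-region contrast is detected by the pooled
two-proportion test. `autoplot()` on a profile draws the per-position
rates with the significant positions highlighted.

Reference arithmetic on published summary values works the same way from
plain tables, e.g. the signed fold for miR-146b from its TPM pair:

```r
signed_fold(2355, 8297)
#> [1] 3.523142
```

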