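---
title: "Methods: comparing small-RNA and DGE libraries between delayed implantation and activation"
author: "delayseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing small-RNA and DGE libraries between delayed implantation and activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delayseq)
```

## The biological setting

Delayed implantation is a hormonally induced arrest of the mouse uterus and
blastocyst at a pre-implantation state; a single estrogen injection releases
the arrest ("activation"). delayseq implements the computational side of a
two-library sequencing comparison of these states: one small-RNA library and
one SAGE-style digital gene expression (DGE) library per condition, tied
together by an integrative analysis of miRNAs and their host and target
genes. Every stage is exposed as a data-frame-in / tibble-out function so
the pipeline can be driven interactively or end to end with
`run_pipeline()`.

## Small-RNA preprocessing

Reads are single-end and carry the 3' sequencing adapter. The 3' end of the
small RNA is defined by the **3'-most exact occurrence of the first 8 nt of
the 3' adapter** (`trim_adapter()`); reads without a perfect 8-nt match are
discarded, as are reads containing `N` (the exact-match rule is undefined
over ambiguity codes). The 5' end of the read is taken verbatim as the 5'
end of the small RNA. Inserts are then size-selected to 18-30 nt — applied
after trimming, since the physical size selection happens on the gel and
the informatic filter can only act on the recovered insert — and collapsed
to unique tags with per-library counts. Accounting is conserved exactly:
input reads = no-adapter discards + length discards + kept counts.

## Nine-way classification

Each unique tag is located in the genome by exact, full-length,
0-mismatch matching on both strands (`map_to_genome()`, backed by
Biostrings). Tags overlapping an annotated interval take the
highest-priority overlapped class in the fixed order miRNA > piRNA > tRNA >
rRNA > snRNA > snoRNA > mRNA; tags that hit the genome outside any interval
are `genomic`, tags with no hit are `unknown`. The priority follows the
conventional listing order of these classes; no tie rule beyond it is
needed because the assignment is deterministic given the annotation.
Independently, any tag that the isomiR module pairs to a mature miRNA is
classified `miRNA`, so sequence variants that no longer match the genome
exactly are not lost to `genomic`/`unknown`. Multi-locus tags count once,
in their single resolved category. The per-library category table is
read-count weighted, with percentages printed to two decimals.

## Differential expression: the pooled two-proportion z-test

Counts are normalised to tags per million (TPM), with the post-filter
library total as denominator. The test statistic, however, always consumes
raw counts: for feature counts $n_1, n_2$ in libraries of total size
$N_1, N_2$, with $\hat p_i = n_i/N_i$ and pooled
$\hat p_0 = (n_1+n_2)/(N_1+N_2)$,

$$ z = \frac{\hat p_1 - \hat p_2}
{\sqrt{\hat p_0 (1-\hat p_0)\left(\tfrac{1}{N_1}+\tfrac{1}{N_2}\right)}} $$

(the classical SAGE-library comparison statistic of Kal et al.). Two-sided
normal p-values are Bonferroni-corrected over the tested features. Fold
changes are reported with the reciprocal-negative convention
(`signed_fold()`): a halving prints as −2.00, never 0.5, and equality as
+1.00. The default screen keeps features with TPM > 100 in either library,
|fold| > 1.2 (miRNAs) or > 2 (genes) and p < 0.001, all strict
inequalities. The filter cuts on the Bonferroni-corrected p by default —
the published methods apply the correction, while the printed tables show
raw-looking p-values — and `p_kind = "raw"` restores the other reading.
Dispersion-based count models are deliberately out of scope: the
two-library design has no replicates to estimate dispersion from.

Two miRNA counting modes exist because published count tables rarely state
one: `all_isomirs` (default) sums every read assigned to a miRNA,
`reference_only` counts reads identical to the mature reference. The two
disagree exactly where isomiRs are abundant — the situation flagged for
miR-21, whose reference sequence moves down between conditions while its
isomiR-inclusive total moves up — and the package keeps both rather than
pretending the discrepancy away.

## IsomiR and editing detection

Tags are paired with candidate mature miRNAs when they share an exact
k-mer; the default k = 7 is the largest value that *guarantees* (by
pigeonhole) a shared k-mer for reads carrying up to two substitutions of a
≥ 21-nt mature, the divergence the assignment step is meant to tolerate.
Larger k (e.g. 12) is faster and configurable but silently drops edits near
the read centre. Candidates are aligned by Needleman–Wunsch with match +1,
mismatch −1, gap opening −2 and gap extension −1, interpreted as affine:
the first symbol of a gap costs −2 and each further symbol −1. The
traceback is deterministic; on exact score ties gap states are preferred
over the diagonal, which places equal-scoring variants at the alignment
ends — a 3'-trimmed read whose final base coincides with the reference's
final base is rendered as a trim, not as an internal deletion plus a match,
the representation used in published isoform tables. Only the
highest-scoring alignment per read is kept (ties: fewer events, then
alphabetical name), and alignments scoring below read length − 8 are left
unassigned; a perfect match scores exactly the read length, so the floor
bounds tolerated divergence at roughly four substitutions' worth of
penalty. miRNAs with known SNPs in the mature sequence can be excluded by
name.

Alignment events split into internal events (substitutions, insertions,
deletions) and end variants (5'/3' trims, 5' extensions, 3' additions).
Only internal substitutions count toward the **editing rate**; end
variants are tallied separately, so a non-templated 3' addition is never
double-counted as a substitution. Per reference position, coverage is the
count-weighted number of reads whose alignment spans the position and the
editing rate is edited/coverage (read-count weighted, matching the
TPM-denominated isoform tables). Rates are standardised to Z-scores, the
median Z across positions is recentred to 0, and each position receives an
upper-tail normal p-value — upper-tail because the question is whether a
position's mismatch rate exceeds the shared background (sequencing error)
under the null that all positions behave alike; positions with p ≤ 0.01
are called edited. Median-centring was chosen over a median/MAD robust
score as the most literal reading of "the median Z-score was set to 0";
with ≥ 3 defined positions and zero spread all Z are 0 and nothing is
significant. Between-condition contrasts over a position set (e.g. the
seed-region positions 4–5) aggregate edited counts and coverage and reuse
the pooled two-proportion z-test.

## DGE: DpnII tags and tag-to-gene mapping

Reference tags are the 16 nt immediately 3' of the 3'-most DpnII site
(`GATC`) on the sense strand; the anchor itself is excluded (published
16-mer tags do not begin with GATC) and transcripts with no site or fewer
than 16 nt downstream yield none. DGE libraries are stranded, so no
antisense rescue is attempted. For tag-to-gene mapping, each supporting
cluster of transcripts is scored by the reliability formula
(#mRNA + #high-throughput mRNA) + 0.5 × #ESTs-with-poly(A), counting
transcripts (not accessions); when more than two clusters claim a tag only
the two best survive (ties by cluster id), while the match class —
single/two/multiple — records the pre-truncation multiplicity. Sequenced
tag pairs of exactly (0,1) or (1,0) across the two libraries are removed
as noise before testing; DE then delegates to the same z-test machinery
with the gene thresholds.

## Integration

Host-gene co-expression is Pearson correlation of log10(TPM+1)-transformed
miRNA versus host values within one library (the published r and p state
no transform; the log scale is the conventional choice for expression
correlations, and Spearman is available as a transform-free check, with
the p-value from the t-transform of r). A **coherent target** is a
predicted target gene whose DE direction opposes its miRNA's; genes
failing the DE screen are "unchanged" and non-coherent, matching the
binary framing. Target predictions are inputs (merged TargetScan/PITA-style
tables), never computed — predicted-target sets are database-version
artefacts. Direction enrichment compares the opposite-direction fraction
among DE predicted targets with the background fraction among all DE
genes by the chi-square (1 df) two-proportion test.

## What the simulator emulates — and what it does not

`simulate_smallrna_libraries()` plants every ground truth downstream
stages need: a toy genome carrying each annotated class, a miRNA catalog
with let-7-dominated abundances, per-miRNA activation/delay folds, a
per-read Bernoulli editing model at chosen positions, 3' end-variant
probabilities, and adapter-bearing fixed-length (36 nt) reads. Reads are
kept collapsed as (sequence, count) — an accepted input form — and the
per-read Bernoulli model is realised exactly as one multinomial over the
enumerated variant space, so depth 10^6 costs no more than depth 10^3.
Default category fractions are the study's delay-library proportions
(miRNA ≈ 74.5%, unknown ≈ 23.8%, the seven minor classes below 1%);
default planted folds mirror the headline miRNA calls (e.g. miR-146b 3.52,
let-7f 1.27, miR-145 −2.56). Editing defaults plant equal rates at
positions 4 and 5 of let-7a — 0.08 per read under delay, 0.02 under
activation — the study's seed-region contrast; equal rates at the two hot
positions keep both positions' median-centred Z comfortably above the
2.33 cutoff by construction (with two unequal hot positions the weaker
one's Z is capped near 2.7 regardless of depth, an intrinsic property of
the scale-invariant statistic). The editing specification carries separate
delay/activation probabilities because the between-condition contrast is
part of the design under study; a single `prob` is accepted for both.

Deliberately not modelled: sequencer error profiles, quality scores, PCR
duplication and ligation bias. Decoy and unknown sequences are screened so
their classification is deterministic (no accidental adapter 8-mers, no
genome hits or shared mature k-mers for unknowns). Passing recovery tests
on these simulations therefore demonstrates the correctness of the
statistics and bookkeeping, not robustness to real-library noise.

`simulate_transcriptome()` plants a GATC-free 16-mer tag and tail behind a
GATC site (screening the tag/tail junction so no spurious downstream site
can form), with configurable tagless transcripts and tags shared across
two or three clusters; `simulate_sage_reads()` draws tag counts with
planted gene folds and adds (1,0)/(0,1) singletons to exercise the filter.
`simulate_host_pairs()` draws a shared latent log-normal factor scaled so
the log-scale correlation equals the target in expectation, and
`simulate_target_predictions()` plants a configurable coherent bias.

## Numerical choices and problem sizes

All randomness flows through R's generator under one seed
(`pipeline_config(seed = ...)`); fixed seeds reproduce every output
byte-identically. Percentages are rounded to two decimals only at the
reporting boundary. Undefined quantities are explicit: zero-coverage
positions carry `NA` rates and are excluded from the Z computation, a
pooled proportion of 0 or 1 yields an `NA` z with a warning, and a zero
TPM denominator reports a signed fold of ±Inf. The shipped tests run the
simulations at 10^3–10^5 reads per library, with one depth-10^6
fold-recovery run over a 1000-miRNA catalog; these sizes were chosen so
the statistical margins (3 binomial SDs; Bonferroni at 0.001) are wide
while the whole suite stays in the minutes range on a single core.

## Known limitations

* The z-test assumes large counts; at very low depth its size is governed
  by the discreteness of the binomial, which is why the type-I checks run
  at expected counts near 100.
* Editing rates conflate genuine modification with any residual
  misassignment between near-identical family members (e.g. let-7a/let-7c
  differ at one position); the highest-score rule plus the k-mer
  pre-filter controls but cannot eliminate cross-mapping.
* The reliability score treats transcripts as independent evidence;
  duplicated submissions inflate it, exactly as in the original scheme.
* Novel-miRNA discovery and target prediction are consumed as inputs,
  never computed.
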