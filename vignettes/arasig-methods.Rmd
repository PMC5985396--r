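---
title: "arasig: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{arasig: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

In androgen-stimulated prostate cancer cells, the androgen receptor (AR) is
a hormone-activated transcription factor. RIP-seq (native RNA
immunoprecipitation with an anti-AR antibody, against a non-specific IgG
control) can ask which long intergenic non-coding RNAs (lincRNAs)
co-precipitate with AR. `arasig` implements the downstream analysis that
such a study needs:

1. call **ARA-lincRNAs** (AR-associated) from RIP-seq counts;
2. build a matched **NonA-lincRNA** control set (RIP ratio near zero);
3. pair every lincRNA with its closest expressed protein-coding neighbor;
4. encode chromatin-mark read densities in ±500 bp TSS windows and ask a
   random forest which marks discriminate ARA from NonA loci, with a
   label-shuffle null on the Gini importances;
5. profile TADs (peak content, gene expression, boundary proximity) and
   enhancer signatures (H3K27ac/H3K27me3 ratio, enhancer-mark stringency
   correlation ladder, peak-to-TSS distances, neighbor-response
   comparisons).

Because the original sequencing data cannot be shipped, the package carries
a synthetic-study generator (`study_config()` / `generate_study()`) that
plants every effect the analysis is meant to recover and records the truth,
so each stage has a parameter-recovery test.

# The count model

`nb_test()` stands in for a DESeq2 call, implemented self-contained:

* **Normalization** — median-of-ratios size factors (`size_factors()`):
  factor~s~ = median over genes with positive geometric mean of
  count~gs~/geomean~g~.
* **Effect size** — `log2fc = log2((mean_num + 0.5)/(mean_den + 0.5))` on
  normalized counts. The 0.5 pseudocount is symmetric and keeps the
  estimate finite for zero groups.
* **Dispersion** — per-gene method of moments
  (`alpha = max((s² - mu)/mu², 0)`) shrunk toward the 5%-trimmed study-wide
  mean with weight `w = df/(df + 8)`, floored at 1e-8. With two replicates
  per condition (`df = 2`, `w = 0.2`) the per-gene estimate is almost
  uninformative, and without shrinkage a Wald test at α = 0.05 rejects
  ~19% of null genes; shrinkage restores near-nominal behavior, which is
  exactly the role dispersion shrinkage plays in DESeq2.
* **Inference** — delta-method standard error of the log2 fold change under
  NB sampling, referred to a **t distribution with df + 8 degrees of
  freedom**: the prior weight of the shrinkage acts like 8 prior degrees of
  freedom. Measured null rejection at 2 v 2 (NB mean 100, dispersion 0.1)
  is ≈ 0.042 at α = 0.05. No LFC shrinkage and no independent filtering are
  applied.
* **Multiplicity** — Benjamini–Hochberg step-up (`bh_adjust()`), written
  out rather than delegated, and tested against a brute-force oracle.

Calling rules reproduce the published thresholds: ARA = `log2fc > 0` and
BH-FDR < 10% (`call_ara()`); androgen-responsive = q < 0.05 and |fold
change| ≥ 2 (`call_differential()`). `build_nona()` excludes genes with
zero counts across either antibody group, removes the ARA set from the pool
(the source procedure implies but does not state this; a control set that
contains positives would be incoherent), sorts by |log2fc| ascending with
lexicographic tie-break, and takes the first *n*.

Constant-count genes are assigned p = 1 outright: a gene identical in every
sample carries no evidence, but its estimated dispersion is 0 and the Wald
statistic would otherwise be undefined or overconfident.

# Intervals and annotation

Internal coordinates are 0-based half-open (BED arithmetic); GTF I/O
converts to/from the 1-based closed dialect. The TSS is stored as the
half-open boundary on the 5′ side (start of the first exon on `+`, end of
the last exon on `-`), so `[tss - flank, tss + flank)` is a symmetric
window for either strand. Where several isoforms exist, gene-level analyses
use the 5′-most TSS per gene.

`count_in_window()` counts reads overlapping a window by ≥ 1 bp and
normalizes to reads per million mapped (RPM). `count_per_gene()` is
union-mode counting: a read overlapping exons of two distinct genes is
ambiguous and counted for neither. `closest_tss()` requires the
protein-coding gene to be expressed (FPKM strictly > 1 in at least one
condition) and breaks exact distance ties toward the downstream candidate,
then lexicographically — both choices the source leaves open.

The novel-lincRNA catalog (`classify_novel_lincrnas()`) approximates an
assembly-based discovery step: "intergenic" means no exonic overlap with
any reference transcript on either strand; retained novel transcripts must
have FPKM ≥ 1, length ≥ 200 nt and pass the coding filter. The coding
filter replaces an SVM coding-potential model with a six-frame longest-ORF
threshold (≥ 100 codons ⇒ coding). This keeps the same filtering role while
staying self-contained; the threshold is configurable and the scan is
tested against an independent translate-and-scan oracle.

# Peak calling

`call_peaks()` scores candidate peaks against a local Poisson background,
in the spirit of HOMER's local filtering: candidates are local maxima of
read-start counts over fixed `peak_width` tiles (default 200 bp — the
candidate rule and width are not specified upstream and are configurable);
the background rate λ comes from a 10-kb window centered on the candidate,
excluding the candidate tile itself (no self-contamination), floored at the
chromosome-wide rate (read deserts); p = P(Poisson(λ) ≥ observed); BH
across candidates with FDR < 0.001; retained overlapping/adjacent tiles are
merged keeping the best p. The upstream procedure reports an FDR threshold
without naming the correction; BH is used for consistency with the rest of
the package.

# The discrimination machinery

`encode_features()` builds, per labeled lincRNA with a neighbor, the vector
of RPM values of every track at the lincRNA TSS window and at the neighbor
TSS window (`<mark>@linc` columns first, then `<mark>@pc`, tracks in input
order). `train_classifier()` grows a random forest per candidate ensemble
size in `c(100, 500, 1000, 10000)` with warm starts (trees are shared
across grid points), Gini splitting, bootstrap sampling, OOB scoring, and
`mtry = floor(sqrt(p))`; the grid size with the best stratified 5-fold CV
accuracy is selected (stratification is our choice; the folds are seeded).
The forest is implemented in C++ inside the package with a self-contained
xoshiro RNG — results are bit-reproducible for a given seed across
platforms, which an external RF library would not guarantee, and no RF
package is assumed to exist in the runtime environment.

`importance_null()` permutes the class labels (1000× at release scale;
≥ 200 in routine testing, below 100 a warning flags cutoff instability) and
retrains a fresh forest of the chosen size per shuffle, recording all Gini
importances. `significant_features()` compares each observed importance to
the **per-feature** 95th percentile of its null sample (strictly greater ⇒
significant). The upstream description of the null is ambiguous between a
pooled and a per-feature cutoff; per-feature is the stricter reading and is
the default. The enrichment direction is the sign of (mean feature value in
ARA rows − mean in NonA rows); "up" means more abundant at the ARA TSS.

Null calibration follows from the construction: with exchangeable features
≈ 5% of features are flagged. Power: one planted mark at fold ≥ 5 with
≥ 150 rows per class ranks in the top 3 importances and is flagged in
≥ 90% of seeds (exercised in the acceptance suite).

# TAD and enhancer profiling

Transcripts are assigned to the TAD containing their TSS (bodies may span
boundaries; all downstream TAD metrics are TSS-based). A TAD containing at
least one ARA lincRNA is ARA-containing *irrespective* of NonA content, and
vice versa, so the two groups overlap by construction. Peaks straddling a
boundary count in every TAD they overlap. Per-mark peak counts are compared
by a one-sided t-test (ARA greater), raw by default with a
length-normalized mode behind a flag (the upstream counting is raw
`bedtools intersect`). The boundary-distance metric is
`100 · min(tss − start, end − tss)/(length/2)` — 0% at a boundary, 100% at
the TAD midpoint. TAD-level expression pools `log2(FPKM + 0.01)` of
protein-coding genes (androgen condition) per group with a one-sided
t-test.

Enhancer statistics: the acetylation ratio is
`log2((RPM_H3K27ac + 1)/(RPM_H3K27me3 + 1))` per TSS window (pseudocount 1
RPM; the source is silent on zero denominators), compared between groups by
a one-sided two-sample KS test. The stringency ladder retains pairs whose
lincRNA TSS carries *both* H3K4me1 and H3K27ac above a threshold and
correlates lincRNA vs neighbor androgen log2 fold changes; ρ is read as
Spearman (the symbol convention; Pearson is available via `method`).
Peak-to-TSS distances use peak midpoints on the `log2(d + 1)` scale.
The neighbor-response comparison keeps lincRNAs with "a Pol II mark at the
TSS": a significant PolII peak overlapping the window when a peak set is
supplied, otherwise RPM > 0.

# What the synthetic generator states — and what it does not

`generate_study()` draws a study in which (defaults in parentheses):

* 1000 lincRNAs and 1000 protein-coding genes are laid out on a 4 × 45 Mb
  toy genome, one pc gene per layout unit, lincRNAs kept ≥ 5 kb from any
  pc locus (intergenic by construction). Planted ARA lincRNAs sit
  17.5–32 kb from their designated neighbor's TSS, others 45–110 kb — the
  short-vs-long contrast the cumulative-distance comparison recovers.
* 20% of lincRNAs are planted AR-associated (`frac_ara`), with RIP
  log2(antiAR/IgG) = 2 ± 0.25 (`rip_log2fc_mean`), NB counts at dispersion
  0.05 over a log-normal baseline (median 100; 3% of genes are forced very
  low so the zero-count exclusion rule has work to do). Two replicates per
  antibody, NB noise only — no batch structure, no GC or length bias.
* Each planted lincRNA carries an enhancer strength s ~ U(0.5, 1). All
  marks except H3K27me3 receive a Poisson pileup within ±150 bp of the
  planted TSS at fold 1 + (`mark_enrichment_fold` − 1)·s over the uniform
  75-bp-read background (fold 5 by default; fold 1 plants nothing). Real
  ChIP tracks have promoter signal at *every* active gene and
  mark-specific backgrounds; the generator's background is uniform, so a
  green discrimination test establishes recovery of a planted contrast,
  not performance on real chromatin.
* Androgen response: lincRNAs are planted up with probability 0.6 (planted
  ARA) or 0.35 (others), down with probability 0.15; pc genes 0.25/0.20 —
  rates chosen so the matched NonA subsets of the two discrimination runs
  are populated, echoing the published study where the NonA set was as
  androgen-responsive as the ARA set. Planted |log2FC| ~ N(2,
  `rnaseq_log2fc_sd`).
* Cis coupling: a planted lincRNA copies its fold change to its designated
  neighbor with probability `1 − 4(1 − c)(1 − s)` (mean `c =
  neighbor_coupling`; stronger enhancers couple more often, and equal to 1
  everywhere when c = 1 so the copy-equality property is exact), flipped in
  sign with probability `repress_frac` (androgen-repressive regulation),
  boosted by `cis_boost` (+0.5 log2) when not flipped, with noise sd
  `coupling_noise_sd · (1.5 − s)`. Designated neighbors of planted
  lincRNAs additionally get a 2^0.75 baseline expression boost — the
  TAD-level expression elevation the analysis is meant to detect; without
  it the effect is diluted below desk-scale detectability.
* TADs partition every chromosome (no gaps, no nesting, minimum length
  150 kb, ~150 per chromosome at the default scale); half the boundaries
  are placed 5–20 kb downstream of randomly chosen planted TSSs, so planted
  lincRNAs sit near boundaries while their upstream neighbors stay inside
  the same TAD.
* FPKM is a scaled transform of the planted expression means — it is
  internally consistent with the counts but not an independent
  quantification.

Scale caveat: a ±500 bp window on a 180 Mb genome with 6 × 10⁵ reads per
track has ~6 RPM of background, far above the 0.5–2 RPM thresholds a 3 Gb
genome motivates. The ladder defaults keep the published thresholds, but
recovery tests at toy scale pass quantile-spread thresholds instead.

# Numerical and procedural choices

* All randomness flows from one root seed through named substreams
  (`substream_seed()`), so inserting a stage does not perturb the others;
  the C++ forest is seeded explicitly and does not touch R's RNG.
* Ties: NonA ranking and closest-TSS both break ties lexicographically (and
  downstream-first for neighbors) for determinism.
* A feature whose observed importance equals its null cutoff exactly is
  *not* significant (strict inequality, as stated).
* Matched NonA subsets for the two discrimination runs take the
  lowest-|log2fc| NonA lincRNAs satisfying the same lincRNA-up /
  neighbor-direction condition, truncated to the ARA subset size — the
  published subsets are described as "selected" without a rule; this is our
  construction.
* `run_study()` skips a discrimination run (with a notice in the report)
  when either class has fewer than `min_rows_per_class` labeled rows, and
  uses the RPM > 0 PolII filter because toy-scale peak sets cover only the
  strongest promoters.

# Known limitations

* The NB test has no LFC shrinkage and assumes a two-level single-factor
  design; multi-factor or batch designs are out of scope.
* The peak caller does not use an input control, call broad domains, or
  collapse duplicate reads.
* The generator plants effects independently per stage; correlations
  present in real data (e.g. mappability, copy number, expression-coupled
  chromatin) are absent, so green tests quantify recovery of the stated
  world only.
* The published mean CV accuracies (0.629/0.597) and headline set sizes
  (7022 expressed lincRNAs, 619 ARA) depend on the deposited sequencing
  data and are deliberately not asserted anywhere.
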