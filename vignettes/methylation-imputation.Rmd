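---
title: "Imputing low-coverage WGBS methylation with gradient-boosted trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing low-coverage WGBS methylation with gradient-boosted trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

WGBS measures the methylation level of a CpG as a binomial proportion:
with $N$ reads covering the site and $M$ of them methylated, the beta
value estimate is $\hat\beta = M/N$, an unbiased estimator of the true
cell-population methylation fraction $\beta$ with conditional variance
$\beta(1-\beta)/N$. Below $N = 10$ the estimate is considered missing.

`methboost` treats imputation as supervised regression on the continuous
beta scale. For a target sample within a cohort of at least three
samples sharing tissue and disease group, each eligible CpG becomes a
row of a feature matrix with:

* **Neighbour features (group N)** — beta values of the nearest
  non-missing CpG upstream and downstream *within the same sample*, and
  the base-pair distances to them. Distance is defined between
  forward-strand dyad start positions, matching the single-coordinate
  representation used throughout (the merged dyad occupies
  `[pos, pos + 2)`).
* **Sample average (group A)** — the unweighted leave-one-out mean beta
  over the *other* cohort samples covering the CpG at ≥ 10×; undefined
  (and the CpG excluded) when fewer than two qualify.
* **Context features (groups P/H/G/C, optionally T/R)** — 0/1 overlap of
  the dyad with ATAC peaks, histone-mark peaks, CpG islands and their
  2 kb shores and further-2 kb shelves, transcript annotations; a
  one-hot encoding of a 13-label chromatin-state segmentation; and
  continuous GC-content / recombination-rate lookups.

The learner is gradient boosting on regression trees (xgboost), trained
on CpGs with depth in $[10, 80]$ (both bounds inclusive; very high depth
indicates mapping artefacts), with a held-out validation set driving
early stopping on RMSE. Raw predictions are clipped to $[0, 1]$ — forced
by beta-value semantics, since tree ensembles can overshoot slightly.
A random forest backend (`ranger`) satisfies the same
fit/predict/importance contract for comparison.

Assumptions worth stating: neighbour correlation and cross-sample
concordance do the heavy lifting, so accuracy degrades for CpGs whose
nearest informative neighbour is far (> 100 bp) and in regions where
samples genuinely diverge; imputation transfers information *within* a
tissue/disease group and should not be applied across heterogeneous
cohorts.

## Eligibility rules

CpGs are excluded from training, testing and imputation when they are
non-autosomal, when either base of the dyad is disturbed by a SNP or an
indel of ≤ 2 bp (longer indels are ignored; a variant's disturbed span
is its reference span), when the dyad overlaps a blacklist region, when
the sample average is undefined, or when an up- or downstream neighbour
is missing entirely (chromosome ends). Chromosome-end rows are dropped
rather than filled with sentinel values, because sentinel magnitudes
would leak ordering information into tree splits. Missing low-coverage
records are never deleted: they keep an `is_missing` flag and either
receive an imputed value or a reason code.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 10× | missingness / imputability threshold |
| training depth band | [10, 80]× | rows eligible for fitting |
| `min_others` | 2 | samples (≥ 10×) needed for the sample average |
| intermediate band | [0.20, 0.80] | sample-average stratum for `rmse_intermediate`, inclusive ends |
| binarization threshold | 0.5 | truth dichotomy for AUROC/AUPRC/accuracy; β = 0.5 counts as methylated |
| depth/beta grid bins | 5× / 0.05 | discordance grid resolution; top beta bin right-closed to include 1.0 |
| `variance_quantile` | 0.75 | strict threshold ("above the third quartile") for high-variance CpGs |
| `min_nonmissing` | 20 | samples with a non-missing beta required before a CpG's variance counts |

Boosting hyperparameters are pinned explicitly in `methboost_params()`
(learning rate 0.3, depth 6, no subsampling, L2 = 1, 150 rounds with
patience 10) rather than inherited silently from the library, so a
serialized model records exactly what produced it. Early stopping on
validation RMSE is our reading of standard practice for "use the
validation set to select the model"; it is the one place the procedure
goes beyond plain library defaults.

## The synthetic cohort generator

Every stage of the package is exercised on simulated cohorts with known
ground truth, generated by `simulate_study()`:

1. CpG positions by geometric inter-arrivals (mean 50 bp, the human
   genome-wide average).
2. A 13-state chromatin segmentation from a renewal process, with
   state-specific frequencies and mean segment lengths (quiescent and
   transcribed states long and frequent, TSS and enhancer states short).
3. A latent tissue methylation profile: a Gaussian copula whose
   correlation decays as $\exp(-d/300\,\mathrm{bp})$, pushed through each
   state's low/mid/high Beta-mixture quantile (TSS-like states low,
   quiescent/transcribed high, enhancers dispersed). The marginal at
   every CpG is exactly the state's mixture.
4. Per-sample true betas
   $\beta_{si} = \kappa\,\ell_i + (1-\kappa)\,e_{si}$ with cross-sample
   concordance $\kappa = 0.9$; the sample-specific deviations $e_{si}$
   are themselves regionally correlated with the same distance decay.
   This matters: real samples differ in *regions* (DMR-like), not at
   isolated CpGs, and it is exactly this regional structure that makes
   neighbour features informative beyond the sample average.
5. Planted high-variance blocks (24 % of CpGs, mean 8 CpGs per block):
   concordance drops to 0.5 and betas become intermediate-centred
   (Beta(2,2) with per-cohort block centres and CpG-level dispersion
   0.15), so across-tissue variance is high, short-range pairwise
   differences exceed the genome-wide ones, and the difference-vs-
   distance profile is flat — the behaviour observed in variable regions
   of real cohorts. The planted mass sits just under one quarter because
   "high variance" is operationally defined as the top quartile of
   across-sample variances; the two definitions are then consistent.
6. Sequencing depth: negative binomial with mean 30× and size 2
   (~15 % of CpGs below 10× marginally), multiplied by a smooth shared
   log-normal coverage-efficiency profile (sd 0.5, 2 kb scale) that
   stands in for mappability/GC bias. The shared profile produces the
   regional, cross-sample-correlated missingness clusters of real WGBS —
   without it, CpGs with a far nearest non-missing neighbour would not
   be systematically harder and the error-versus-distance pattern of
   real data would not emerge. Methylated counts are
   $\mathrm{Binomial}(N_{si}, \beta_{si})$.
7. Context tracks placed correlated with the low-methylation states
   (ATAC/H3K4me3/CGI over TSS-like segments, H3K27ac over enhancers,
   exons over transcribed states), GC and recombination tiles, and
   array-style reference betas: truth plus truncated Gaussian noise on a
   random ~3 % probe subset, depth-independent by construction.

All randomness flows from one seed through named substreams, so each
stage is independently reproducible.

What the generator does **not** emulate: sequence-level features (no
FASTA; motif/TFBS tracks are placed, not scanned), state-dependent CpG
density (CpG islands are not denser than quiescent regions here),
non-binomial technical error (bisulfite conversion failure, mapping
bias beyond the smooth coverage profile), and real LD-like structure in
variant positions. Tests passing on these cohorts therefore demonstrate
the correctness of the machinery and the qualitative behaviours above,
not clinical-grade accuracy numbers for any particular tissue.

## Numerical and design choices

* Coordinates are 0-based, half-open (BED convention) everywhere; the
  bedGraph start column is the CpG position. VCF positions are converted
  from 1-based on input.
* The percent column of methylation bedGraphs is never trusted: betas
  are recomputed from counts, and a discrepancy > 0.5 percentage points
  warns (counts win).
* Whether extraction-time coverage cutoffs drop or zero low-coverage
  records differs between tools; this package retains all records and
  relies on `is_missing` flags.
* The dyad-disturbance check covers both bases of the CpG (`pos` and
  `pos + 1`), the conservative reading of "the CG dinucleotide on either
  strand".
* AUROC uses midrank tie handling — betas are ratios of small integers,
  so ties are heavy and naive tie handling visibly biases the statistic.
  Truth with β exactly 0.5 counts as methylated (the only symmetric
  choice once a 0.5 threshold is fixed). Classification metrics over all
  rows (not excluding intermediate truths) are the default; callers can
  pre-filter if they want the other convention.
* `rmse_intermediate` masks on the *sample average*, never on the target
  beta — masking on the target would leak the quantity being predicted
  into the stratum definition.
* The variance-block threshold uses the type-7 sample quantile and a
  strict `>`; "consecutive CpGs" means adjacent in the genome-wide CpG
  index with no base-pair gap limit.
* Pairwise-difference sampling: maximal same-state runs are enumerated,
  runs are sampled uniformly, and all within-run pairs with span
  ≤ 1000 bp are emitted until the per-state budget is met. The span cap
  covers the distance range over which the correlation structure is
  informative; beyond roughly two decay lengths the mean difference
  saturates.
* Variable-importance ties break lexicographically by feature name, so
  rankings are deterministic; multi-run rankings aggregate by summed
  gain.
* Repeated benchmarking resamples train/validation/test independently
  per seed (the natural reading of "repeated random subsampling");
  decile-balanced training uses stratified quotas with proportional
  redistribution when a decile cannot fill its quota.
* Continuous features absent at a CpG stay NA (handled natively by the
  boosting backend) rather than zero-filled — zero is a meaningful GC
  value. The random forest backend cannot consume NA, but the default
  feature groups never produce any.
* The full TFBS registry of a real study (hundreds of factor tracks) is
  configuration, not code: tracks are merged per factor and intersected
  with open chromatin once at bundle load.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen to
preserve all the qualitative orderings: cohorts of 12 samples on a 1 Mb
chromosome (~20,000 CpGs), ten-seed benchmarks with 5,000-CpG splits,
and a 58-sample five-cohort study on 0.5 Mb for the across-tissue
variance analysis. The pipeline scales linearly in CpGs and samples; the
same code runs genome-scale cohorts with 10^6-CpG training splits.

## Known limitations

* Per-sample models do not share information across samples beyond the
  sample-average feature; a pooled-training option exists but per-sample
  training is the default.
* Interpretability is limited: boosting spreads gain across correlated
  features, so importance rankings under-report features that are
  individually informative but redundant.
* CpGs absent from the input table entirely are never imputed — the
  method fills in low-quality *measured* sites, it does not predict the
  whole genome from a sparse assay.
* Accuracy claims transfer to real data only to the extent the generator
  emulates it; see the generator section above.
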