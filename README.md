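# methboost

Gradient-boosted imputation of low-coverage DNA methylation estimates in
multi-sample whole-genome bisulfite sequencing (WGBS).

## The problem

WGBS estimates the methylation level of a CpG — its *beta value* — as the
ratio of methylated to total reads covering it, β̂ = M/N. At sequencing
depth below ~10× this ratio is too coarse and too noisy to be useful
(N = 8 reads can only yield multiples of 1/8), and even deeply sequenced
cohorts routinely leave 10–40 % of the ~26 million autosomal CpGs below
that threshold in any given sample. Analysts either discard those CpGs or
impute them.

`methboost` imputes them. It exploits three strong regularities of
methylation data:

1. **Neighbour correlation** — the beta values of nearby CpGs are highly
   correlated, decaying with distance (most informative within ~100 bp).
2. **Cross-sample concordance** — most CpGs are consistently methylated
   across samples of the same tissue and disease group, so the
   leave-one-out *sample average* at a CpG (mean beta over the other
   adequately covered samples of the cohort) is a powerful predictor.
3. **Genomic context** — chromatin states, open chromatin (ATAC peaks),
   histone marks and CpG-island annotation carry systematic methylation
   information (TSS-like contexts low, quiescent/transcribed high).

A gradient-boosted regression-tree model (xgboost backend; random forest
available) is trained per sample on its own high-confidence CpGs
(depth 10–80×) against the continuous beta target in [0, 1], using the
nearest non-missing neighbour betas and distances (group `N`), the
leave-one-out sample average (`A`), and binary context features (`P`
ATAC, `H` histone marks, `G` general annotations, `C` 13 chromatin
states, plus optional `T` TFBS and `R` recombination rate). The fitted
model then replaces the beta values of eligible low-coverage CpGs, with
full provenance (original value, prediction, reason codes for CpGs that
cannot be imputed).

The package also implements the surrounding evaluation framework —
RMSE on all CpGs and on the intermediate-methylation stratum (sample
average in [0.20, 0.80]), AUROC/AUPRC/accuracy against betas binarized
at 0.5, absolute error as a function of distance to the nearest
informative neighbour, WGBS-versus-array discordance grids (RMSD binned
by 5× depth and 0.05 beta intervals) before and after imputation,
pairwise beta differences by chromatin state, and detection of blocks of
consecutive CpGs with high across-tissue variance — together with a
synthetic WGBS cohort generator with known ground truth, so the entire
pipeline is testable without any external data.

## Worked example

Simulate a 12-sample cohort on a 1 Mb chromosome (~20,000 CpGs, ~50 bp
mean spacing, ~30× coverage), build the feature matrix for one sample,
benchmark with repeated random subsampling, and impute:

```r
library(methboost)

cfg <- sim_config(seed = 1, n_samples = 12, chrom_length = 1e6)
sim <- simulate_cohort(cfg)

fm <- assemble_matrix(sim$cohort, "tissueA_NGT_s01", sim$bundle)
report <- repeated_benchmark(fm, sizes = c(4500, 4500, 4500),
                             n_repeats = 10, base_seed = 201)
print(report)
#> benchmark_report: 10 repeat(s), xgboost backend, features: all
#>   rmse_all           0.08397 +/- 0.00141
#>   rmse_intermediate  0.13757 +/- 0.00292
#>   auroc              0.98065 +/- 0.00120
#>   auprc              0.99613 +/- 0.00026
#>   accuracy           0.93849 +/- 0.00244

model <- methboost(fm, seed = 1)
imputed <- impute_sample(sim$cohort$tables[[1]], sim$cohort, sim$bundle,
                         model, quiet = FALSE)
#> imputed 4128 CpGs; unimputable: insufficient_cohort_support=43, no_neighbor=1
```

`rmse_all` is the root-mean-squared error of predicted versus observed
beta on held-out test CpGs; `rmse_intermediate` the same restricted to
CpGs whose cross-sample average lies in [0.20, 0.80] (the
biologically-variable stratum, intrinsically harder); AUROC/AUPRC score
the continuous predictions against betas binarized at 0.5. Because the
cohort is simulated, the imputed values can also be compared with the
generative truth: on this run the mean absolute error at imputed sites
drops from 0.091 (raw low-coverage estimates) to 0.035 after imputation.

`variable_importance(model)` ranks features by total split gain; on
cohorts with realistic cross-sample concordance the sample average ranks
first, followed by the neighbour betas — with `plot(model)` for a quick
bar chart.

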