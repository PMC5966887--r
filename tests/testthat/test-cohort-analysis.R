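test_that("missingness by state normalizes within each state", {
  st <- data.frame(chrom = "chr1", start = c(0L, 400L), end = c(400L, 800L),
                   label = c("Quiescent", "TSS_Active"))
  t <- toy_table(pos = c(10L, 110L, 210L, 310L, 410L, 510L),
                 n_meth = 0L, n_total = c(5L, 20L, 20L, 20L, 20L, 20L))
  ms <- missingness_by_state(t, st)
  expect_equal(ms$fraction[ms$state == "Quiescent"], 0.25)
  expect_equal(ms$fraction[ms$state == "TSS_Active"], 0)
  # group-by oracle on simulated data
  sim <- sim_small()
  t2 <- sim$cohort$tables[[3]]
  ms2 <- missingness_by_state(t2, sim$bundle$state_track)
  b <- annotation_bundle(state_track = sim$bundle$state_track)
  lab <- state_at(b, t2$chrom, t2$pos)
  for (i in sample(nrow(ms2), 5)) {
    s <- ms2$state[i]
    sel <- !is.na(lab) & lab == s
    if (ms2$state[i] == "unannotated") sel <- is.na(lab)
    expect_equal(ms2$n_total[i], sum(sel))
    expect_equal(ms2$n_missing[i], sum(sel & t2$is_missing))
  }
})

test_that("pairwise differences enumerate within-run pairs exhaustively", {
  st <- data.frame(chrom = "chr1", start = 0L, end = 1000L, label = "Quiescent")
  mb <- data.frame(chrom = "chr1", pos = c(0L, 10L, 30L),
                   beta = c(0.1, 0.2, 0.5))
  pd <- pairwise_differences(mb, st, n_pairs = 100, seed = 1, max_span = 1e6)
  expect_equal(nrow(pd), 3L)
  got <- pd[order(pd$distance), ]
  expect_equal(got$distance, c(10, 20, 30))
  expect_equal(got$abs_diff, c(0.1, 0.3, 0.4), tolerance = 1e-12)
  # constant betas: all differences zero
  mb2 <- mb; mb2$beta <- 0.4
  pd2 <- pairwise_differences(mb2, st, n_pairs = 100, seed = 1)
  expect_true(all(pd2$abs_diff == 0))
})

test_that("pairs never straddle states, chromosomes, or the span cap", {
  st <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   start = c(0L, 500L, 0L), end = c(500L, 1000L, 1000L),
                   label = c("A", "B", "A"))
  set.seed(14)
  mb <- data.frame(
    chrom = rep(c("chr1", "chr2"), c(40, 20)),
    pos = c(sort(sample(0:999, 40)), sort(sample(0:999, 20))),
    beta = runif(60))
  pd <- pairwise_differences(mb, st, n_pairs = 1e4, seed = 2, max_span = 300)
  expect_true(all(pd$distance <= 300))
  # oracle: exhaustive all-pairs enumeration with the same constraints
  b <- annotation_bundle(state_track = st)
  lab <- state_at(b, mb$chrom, mb$pos)
  n_oracle <- 0L
  for (i in 1:59) for (j in (i + 1):60) {
    same_run <- mb$chrom[i] == mb$chrom[j] && !is.na(lab[i]) &&
      !is.na(lab[j]) && lab[i] == lab[j] &&
      all(lab[i:j] == lab[i], na.rm = FALSE) &&
      all(mb$chrom[i:j] == mb$chrom[i])
    if (isTRUE(same_run) && mb$pos[j] - mb$pos[i] <= 300)
      n_oracle <- n_oracle + 1L
  }
  expect_equal(nrow(pd), n_oracle)
})

test_that("variance blocks recover a forced toy run", {
  # variances per CpG: .01 .05 .06 .07 .01 .02 (3 samples, symmetric spread)
  d <- sqrt(c(.01, .05, .06, .07, .01, .02))
  beta <- cbind(0.5 - d, 0.5, 0.5 + d)
  co <- toy_cohort(pos = c(0L, 50L, 100L, 150L, 200L, 250L) + 10L,
                   beta_mat = beta, depth = 1000L)
  bl <- find_high_variance_blocks(co, min_nonmissing = 3,
                                  variance_quantile = 0.5)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$cpg_count, 3L)
  expect_equal(bl$start, 60L)
  expect_equal(bl$end, 162L)
  # all variances equal: nothing strictly above the quantile
  co2 <- toy_cohort(pos = c(10L, 60L, 110L),
                    beta_mat = cbind(0.4, 0.5, 0.6)[rep(1, 3), ],
                    depth = 1000L)
  expect_equal(nrow(find_high_variance_blocks(co2, min_nonmissing = 3)), 0L)
  expect_error(find_high_variance_blocks(co, min_nonmissing = 99), "exceeds")
})

test_that("block finding ignores sample order and all-missing samples", {
  sim <- sim_small()
  co <- sim$cohort
  b1 <- find_high_variance_blocks(co, min_nonmissing = 3)
  perm <- rev(seq_len(ncol(co$beta)))
  co2 <- co
  co2$beta <- co$beta[, perm]; co2$depth <- co$depth[, perm]
  co2$tables <- co$tables[perm]
  b2 <- find_high_variance_blocks(co2, min_nonmissing = 3)
  expect_equal(as.data.frame(b1), as.data.frame(b2))
  # adding an all-missing sample changes nothing
  t_all_missing <- methyl_table(
    data.frame(chrom = co$index$chrom, pos = co$index$pos,
               n_meth = 0L, n_total = 1L),
    sample_id = "empty", tissue = co$tissue, disease_state = co$disease_state)
  co3 <- cohort_set(c(co$tables, list(t_all_missing)))
  b3 <- find_high_variance_blocks(co3, min_nonmissing = 3)
  expect_equal(as.data.frame(b1), as.data.frame(b3))
})

test_that("discordance grid cells match hand arithmetic and a group-by oracle", {
  primary <- data.frame(chrom = "chr1", pos = c(10L, 20L),
                        beta = c(0.70, 0.90), depth = c(12L, 13L))
  reference <- data.frame(chrom = "chr1", pos = c(10L, 20L), beta = 0.80)
  g <- discordance_grid(primary, reference)
  expect_equal(nrow(g), 1L)
  expect_equal(g$rmsd, 0.1, tolerance = 1e-12)
  expect_equal(g$n, 2L)
  # identity: all-zero grid
  ref2 <- data.frame(chrom = "chr1", pos = c(10L, 20L), beta = c(0.70, 0.90))
  g2 <- discordance_grid(primary, ref2)
  expect_true(all(g2$rmsd == 0))
  # randomized group-by oracle; total n equals the inner-join size
  set.seed(15)
  n <- 800
  p <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L,
                  beta = runif(n), depth = rpois(n, 25))
  r <- data.frame(chrom = "chr1", pos = sample(p$pos, 500), beta = runif(500))
  g3 <- discordance_grid(p, r)
  expect_equal(sum(g3$n), 500L)
  join <- merge(p, r, by = c("chrom", "pos"))
  for (i in sample(nrow(g3), 8)) {
    sel <- join$depth >= g3$depth_bin_start[i] &
      join$depth < g3$depth_bin_start[i] + 5 &
      (join$beta.y >= g3$beta_bin_start[i] &
         (join$beta.y < g3$beta_bin_start[i] + 0.05 |
            g3$beta_bin_start[i] == 0.95))
    expect_equal(g3$n[i], sum(sel))
    expect_equal(g3$rmsd[i], sqrt(mean((join$beta.x - join$beta.y)[sel]^2)),
                 tolerance = 1e-10)
  }
  # row-order invariance
  o <- sample(n)
  g4 <- discordance_grid(p[o, ], r)
  expect_equal(as.data.frame(g3), as.data.frame(g4))
  expect_error(discordance_grid(p, data.frame(chrom = "chr9", pos = 1L,
                                              beta = 0.5)), "shared")
})

test_that("grid differences subtract cellwise with sign before-minus-after", {
  set.seed(16)
  p <- data.frame(chrom = "chr1", pos = 1:300 * 10L, beta = runif(300),
                  depth = rpois(300, 20))
  r <- data.frame(chrom = "chr1", pos = 1:300 * 10L, beta = runif(300))
  g <- discordance_grid(p, r)
  d0 <- grid_difference(g, g)
  expect_true(all(d0$delta_rmsd == 0))
  # after all-zero: difference equals before
  p_perfect <- p; p_perfect$beta <- r$beta
  g_after <- discordance_grid(p_perfect, r)
  d <- grid_difference(g, g_after)
  key <- paste(d$depth_bin_start, d$beta_bin_start)
  gkey <- paste(g$depth_bin_start, g$beta_bin_start)
  expect_equal(d$delta_rmsd, g$rmsd[match(key, gkey)], tolerance = 1e-12)
  g_other <- discordance_grid(p, r, depth_bin = 10)
  expect_error(grid_difference(g, g_other), "binning")
})

test_that("feature correlations match the textbook formula", {
  fm <- fm_mid()
  feats <- c("sample_average", "beta_up", "atac_peak")
  cm <- feature_correlation_matrix(fm, feats)
  expect_equal(dim(cm), c(4L, 4L))
  man <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_equal(cm["beta", "sample_average"],
               man(fm$target, fm$sample_average), tolerance = 1e-10)
  expect_equal(cm["beta_up", "atac_peak"],
               man(fm$beta_up, fm$atac_peak), tolerance = 1e-10)
  # forced correlations
  fm2 <- fm
  fm2$mirror <- 1 - fm2$target
  attr(fm2, "feature_names") <- c(attr(fm, "feature_names"), "mirror")
  cm2 <- feature_correlation_matrix(fm2, "mirror")
  expect_equal(cm2["beta", "mirror"], -1, tolerance = 1e-12)
})
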