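test_that("config validation rejects impossible settings before output", {
  expect_error(sim_config(mean_spacing = 0), "mean_spacing")
  expect_error(sim_config(kappa = 1.5), "kappa")
  expect_error(sim_config(n_samples = 2), "cohorts")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("full concordance collapses samples onto the tissue latent", {
  cfg <- sim_config(seed = 3, n_samples = 3, chrom_length = 5e4, kappa = 1,
                    block_fraction = 0)
  sim <- simulate_cohort(cfg)
  tb <- sim$truth$true_beta[[1]]
  expect_equal(tb[, 1], tb[, 2], tolerance = 1e-12)
  expect_equal(tb[, 1], tb[, 3], tolerance = 1e-12)
  # with full depth everywhere the sample average equals the shared truth
  arr <- simulate_array(sim$truth, colnames(tb)[1], noise_sd = 0,
                        probe_fraction = 1)
  expect_equal(arr$beta, unname(tb[, 1]), tolerance = 1e-12)
})

test_that("CpG counts follow the geometric-spacing expectation", {
  cfg <- sim_config(seed = 5, n_samples = 3, chrom_length = 1e6,
                    mean_spacing = 50)
  sim <- simulate_cohort(cfg)
  n <- nrow(sim$truth$index)
  expected <- 1e6 / 50
  sd5 <- 5 * sqrt(1e6 * (1 / 50) * (1 - 1 / 50))  # per-bp Bernoulli count sd
  expect_gt(n, expected - sd5)
  expect_lt(n, expected + sd5)
  gaps <- diff(sim$truth$index$pos)
  expect_equal(mean(gaps), 50, tolerance = 0.1)
})

test_that("true betas are bimodal with most mass at the extremes", {
  sim <- sim_small()
  tb <- sim$truth$true_beta[[1]]
  outside <- !sim$truth$in_block
  frac_extreme <- mean(tb[outside, ] < 0.2 | tb[outside, ] > 0.8)
  expect_gte(frac_extreme, 0.6)
  # planted blocks are enriched for intermediate values instead
  frac_int_block <- mean(tb[!outside, ] >= 0.2 & tb[!outside, ] <= 0.8)
  expect_gt(frac_int_block, frac_extreme / 2)
  expect_gt(frac_int_block, mean(tb[outside, ] >= 0.2 & tb[outside, ] <= 0.8))
})

test_that("observed betas are unbiased binomial estimates of the truth", {
  sim <- sim_small()
  co <- sim$cohort
  tb <- sim$truth$true_beta[[1]]
  obs <- co$beta; tru <- tb
  ok <- !is.na(obs) & co$depth > 0
  diffs <- (obs - tru)[ok]
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("beta-estimate RMSD shrinks with depth like a binomial", {
  sim <- sim_small()
  co <- sim$cohort
  tru <- sim$truth$true_beta[[1]]
  for (d in c(10, 20, 30)) {
    sel <- co$depth >= d & co$depth < d + 5 & !is.na(co$beta)
    obs_rmsd <- sqrt(mean((co$beta[sel] - tru[sel])^2))
    dd <- co$depth[sel]
    pred_rmsd <- sqrt(mean(tru[sel] * (1 - tru[sel]) / dd))
    expect_lt(abs(obs_rmsd - pred_rmsd) / pred_rmsd, 0.2)
  }
})

test_that("array simulation is depth-independent with binomial probe counts", {
  sim <- sim_small()
  sid <- colnames(sim$truth$true_beta[[1]])[2]
  arr <- simulate_array(sim$truth, sid, noise_sd = 0, probe_fraction = 0.03,
                        seed = 99)
  n_cpg <- nrow(sim$truth$index)
  expected <- 0.03 * n_cpg
  expect_lt(abs(nrow(arr) - expected), 5 * sqrt(expected))
  # noiseless probes equal truth exactly
  ti <- match(paste(arr$chrom, arr$pos),
              paste(sim$truth$index$chrom, sim$truth$index$pos))
  expect_equal(arr$beta, unname(sim$truth$true_beta[[1]][ti, sid]),
               tolerance = 1e-12)
  expect_error(simulate_array(sim$truth, sid, noise_sd = -1), "noise_sd")
})

test_that("raw-WGBS-vs-array discordance falls with sequencing depth", {
  sim <- sim_small()
  co <- sim$cohort
  sid <- names(co$tables)[1]
  arr <- simulate_array(sim$truth, sid, noise_sd = 0, probe_fraction = 0.5,
                        seed = 31)
  t <- co$tables[[sid]]
  primary <- data.frame(chrom = t$chrom, pos = t$pos, beta = t$beta,
                        depth = t$n_total)
  g <- discordance_grid(primary, arr[, c("chrom", "pos", "beta")])
  # average rmsd (weighted) per depth bin decreases from low to high depth
  agg <- tapply(g$rmsd * g$n, g$depth_bin_start, sum) /
    tapply(g$n, g$depth_bin_start, sum)
  dep <- as.numeric(names(agg))
  low <- mean(agg[dep < 10], na.rm = TRUE)
  mid <- mean(agg[dep >= 10 & dep < 30], na.rm = TRUE)
  high <- mean(agg[dep >= 30 & dep < 60], na.rm = TRUE)
  expect_gt(low, mid)
  expect_gt(mid, high)
})

test_that("simulation writes every consumable file format", {
  cfg <- sim_config(seed = 17, n_samples = 3, chrom_length = 3e4)
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_simulation(study, dir)
  files <- list.files(dir)
  expect_true(any(grepl("\\.bedGraph$", files)))
  expect_true("chromatin_states.bed" %in% files)
  expect_true(any(startsWith(files, "truth_")))
  # bedGraphs read back into the same cohort
  t0 <- study$cohorts[[1]]$tables[[1]]
  back <- read_methylation_bedgraph(
    file.path(dir, paste0(attr(t0, "sample_id"), ".bedGraph")),
    dialect = "methyldackel")
  expect_equal(back$n_meth, t0$n_meth)
  expect_equal(back$n_total, t0$n_total)
})

test_that("identical seeds reproduce the study; different seeds differ", {
  cfg <- sim_config(seed = 23, n_samples = 3, chrom_length = 3e4)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth$true_beta, s2$truth$true_beta)
  expect_identical(s1$cohorts[[1]]$beta, s2$cohorts[[1]]$beta)
  s3 <- simulate_study(sim_config(seed = 24, n_samples = 3,
                                  chrom_length = 3e4))
  expect_false(identical(s1$truth$true_beta, s3$truth$true_beta))
})
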