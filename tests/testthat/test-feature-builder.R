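test_that("nearest non-missing neighbours skip missing CpGs", {
  t <- toy_table(pos = c(100L, 150L, 155L, 160L),
                 n_meth = c(4L, 1L, 0L, 18L),
                 n_total = c(20L, 20L, 5L, 20L))   # 155 is missing (<10x)
  nb <- neighbor_features(t)
  expect_equal(nb$beta_up[2], 0.2)
  expect_equal(nb$dist_up[2], 50)
  expect_equal(nb$beta_down[2], 0.9)
  expect_equal(nb$dist_down[2], 10)
  # chromosome boundary: first CpG lacks upstream, flagged incomplete
  expect_true(is.na(nb$beta_up[1]))
  expect_false(nb$complete[1])
})

test_that("neighbour features equal a linear-scan oracle on a random chromosome", {
  set.seed(21)
  n <- 1000
  pos <- sort(sample(1e5, n))
  n_total <- rnbinom(n, mu = 30, size = 2)
  t <- toy_table(pos = pos, n_meth = rbinom(n, n_total, 0.5), n_total = n_total)
  nb <- neighbor_features(t)
  good <- !t$is_missing & !is.na(t$beta)
  for (i in sample(n, 60)) {
    up <- which(good & seq_len(n) < i)
    dn <- which(good & seq_len(n) > i)
    if (length(up) > 0) {
      j <- max(up)
      expect_identical(nb$beta_up[i], t$beta[j])
      expect_identical(nb$dist_up[i], as.numeric(pos[i] - pos[j]))
    } else expect_true(is.na(nb$beta_up[i]))
    if (length(dn) > 0) {
      j <- min(dn)
      expect_identical(nb$beta_down[i], t$beta[j])
      expect_identical(nb$dist_down[i], as.numeric(pos[j] - pos[i]))
    } else expect_true(is.na(nb$beta_down[i]))
  }
  expect_true(all(nb$dist_up[!is.na(nb$dist_up)] > 0))
  expect_true(all(nb$dist_down[!is.na(nb$dist_down)] > 0))
})

test_that("neighbours never cross a chromosome boundary", {
  t <- methyl_table(data.frame(chrom = rep(c("chr1", "chr2"), each = 2),
                               pos = c(10L, 60L, 10L, 60L),
                               n_meth = c(2L, 4L, 6L, 8L), n_total = 20L),
                    sample_id = "s")
  nb <- neighbor_features(t)
  expect_true(is.na(nb$beta_up[3]))   # first CpG of chr2
  expect_true(is.na(nb$beta_down[2])) # last CpG of chr1
})

test_that("cross-sample average follows the leave-one-out >= 10x rule", {
  # others: betas 0.8 (15x), 0.6 (10x), 0.9 (5x) -> mean(0.8, 0.6) = 0.7
  beta <- matrix(c(0.5, 0.8, 0.6, 0.9), 1, 4)
  depth <- matrix(c(30L, 15L, 10L, 5L), 1, 4)
  co <- toy_cohort(pos = 100L, beta_mat = beta, depth = depth)
  expect_equal(sample_average(co, "chr1", 100L, "s1"), 0.7)
  # only one other sample adequately covered -> undefined
  depth2 <- matrix(c(30L, 15L, 5L, 5L), 1, 4)
  co2 <- toy_cohort(pos = 100L, beta_mat = beta, depth = depth2)
  expect_true(is.na(sample_average(co2, "chr1", 100L, "s1")))
  expect_error(sample_average(co, "chr1", 100L, "nope"), "unknown")
})

test_that("identical cohort betas give the shared beta as average everywhere", {
  pos <- c(10L, 60L, 110L)
  beta <- matrix(0.25, 3, 4)
  co <- toy_cohort(pos = pos, beta_mat = beta, depth = 20L)
  for (p in pos) expect_equal(sample_average(co, "chr1", p, "s2"), 0.25)
})

test_that("sample average excludes the target: perturbing it changes nothing", {
  sim <- sim_small()
  co <- sim$cohort
  sid <- names(co$tables)[1]
  a1 <- methboost:::sample_average_all(co, sid)
  co2 <- co
  co2$beta[, sid] <- runif(nrow(co2$beta))     # corrupt the target column
  a2 <- methboost:::sample_average_all(co2, sid)
  expect_identical(a1, a2)
  # order invariance over cohort samples
  co3 <- co
  perm <- rev(seq_len(ncol(co$beta)))
  co3$beta <- co$beta[, perm]; co3$depth <- co$depth[, perm]
  co3$tables <- co$tables[perm]
  expect_equal(a1, methboost:::sample_average_all(co3, sid))
})

test_that("feature-set selection yields the documented column counts", {
  sim <- sim_small()
  sid <- names(sim$cohort$tables)[1]
  fmA <- assemble_matrix(sim$cohort, sid, sim$bundle, feature_set = "A")
  expect_identical(attr(fmA, "feature_names"), "sample_average")
  fmAN <- assemble_matrix(sim$cohort, sid, sim$bundle, feature_set = c("A", "N"))
  expect_length(attr(fmAN, "feature_names"), 5L)
  expect_setequal(attr(fmAN, "feature_names"),
                  c("sample_average", "beta_up", "beta_down",
                    "dist_up", "dist_down"))
  expect_error(assemble_matrix(sim$cohort, sid, sim$bundle,
                               feature_set = "Z"), "unknown feature group")
})

test_that("the default matrix has no undefined feature values and bounded columns", {
  fm <- fm_mid()
  feats <- attr(fm, "feature_names")
  # registry bookkeeping: A (1) + N (4) + context columns of groups P,H,G,C
  b <- sim_mid()$bundle
  n_ctx <- sum(b$groups %in% c("P", "H", "G")) + length(b$states)
  expect_length(feats, 5L + n_ctx)
  x <- as.matrix(as.data.frame(fm)[, feats])
  expect_false(anyNA(x))
  for (cl in c("sample_average", "beta_up", "beta_down"))
    expect_true(all(fm[[cl]] >= 0 & fm[[cl]] <= 1))
  expect_true(all(fm$dist_up > 0 & fm$dist_down > 0))
  onehots <- feats[startsWith(feats, "state_")]
  expect_true(all(rowSums(as.data.frame(fm)[, onehots]) <= 1))
})

test_that("mean pairwise |difference| increases with distance on simulated data", {
  sim <- sim_small()
  co <- sim$cohort
  mean_beta <- rowMeans(ifelse(co$depth >= 10, co$beta, NA), na.rm = TRUE)
  keep <- !sim$truth$in_block & is.finite(mean_beta)
  pos <- co$index$pos[keep]; mb <- mean_beta[keep]
  # consecutive-pair differences binned by gap
  d <- diff(pos); dd <- abs(diff(mb))
  bins <- cut(d, c(0, 50, 150, 400), right = TRUE)
  m <- tapply(dd, bins, mean)
  expect_true(all(diff(m) > 0))
})
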