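test_that("split plans are disjoint, exactly sized, and seed-reproducible", {
  p <- make_split(10, c(3, 3, 3), seed = 1)
  expect_length(p$train_idx, 3); expect_length(p$val_idx, 3)
  expect_length(p$test_idx, 3)
  expect_length(intersect(p$train_idx, c(p$val_idx, p$test_idx)), 0)
  expect_length(intersect(p$val_idx, p$test_idx), 0)
  expect_identical(make_split(1e6, c(1000, 1000, 1000), seed = 5),
                   make_split(1e6, c(1000, 1000, 1000), seed = 5))
  a <- make_split(1e6, c(1000, 1000, 1000), seed = 5)
  b <- make_split(1e6, c(1000, 1000, 1000), seed = 6)
  expect_false(identical(a$train_idx, b$train_idx))
  expect_error(make_split(9, c(3, 3, 4), seed = 1), "eligible")
  expect_warning(make_split(9, c(3, 3, 4), seed = 1, scale = TRUE), "scaled")
  expect_error(make_split(10, c(3, 0, 3), seed = 1), "positive")
})

test_that("a perfectly informative feature is learnt nearly exactly", {
  fm <- fm_mid()
  fm$target <- fm$sample_average      # plant the generative identity
  m <- methboost(fm, features = "A", seed = 3)
  rows <- which(fm$trainable)
  test_rows <- rows[seq(1, length(rows), by = 3)]
  pred <- as.numeric(predict(m, methboost:::fm_subset(fm, test_rows)))
  expect_lt(rmse(pred, fm$target[test_rows]), 0.02)
})

test_that("constant targets give constant predictions and near-zero RMSE", {
  fm <- fm_mid()
  fm$target <- 0.7
  m <- methboost(fm, seed = 3)
  pred <- as.numeric(predict(m, methboost:::fm_subset(fm, which(fm$trainable))))
  expect_true(all(abs(pred - 0.7) < 0.01))
})

test_that("shuffled targets are unlearnable: held-out RMSE near target sd", {
  set.seed(13)
  fm <- fm_mid()
  rows <- which(fm$trainable)
  fm$target[rows] <- sample(fm$target[rows])
  n <- length(rows)
  plan <- make_split(n, c(floor(n * .6), floor(n * .2), floor(n * .2)),
                     seed = 2)
  m <- methboost(fm, plan = plan, seed = 2)
  test_rows <- rows[plan$test_idx]
  pred <- as.numeric(predict(m, methboost:::fm_subset(fm, test_rows)))
  expect_lt(abs(rmse(pred, fm$target[test_rows]) - sd(fm$target[rows])),
            0.1 * sd(fm$target[rows]))
})

test_that("predictions are clipped into [0,1] and row-order invariant", {
  m <- model_mid()
  fm <- fm_mid()
  pred <- predict(m, fm)
  expect_true(all(pred >= 0 & pred <= 1))
  o <- sample(nrow(fm))
  pred_perm <- predict(m, methboost:::fm_subset(fm, o))
  expect_equal(as.numeric(pred_perm), as.numeric(pred)[o], tolerance = 1e-12)
  expect_error(predict(m, fm_mid()[, 1:3]), "missing feature")
})

test_that("test rows never influence fitting", {
  fm <- fm_mid()
  rows <- which(fm$trainable)
  n <- length(rows)
  plan <- make_split(n, c(2000, 500, 500), seed = 9)
  m1 <- methboost(fm, plan = plan, seed = 9)
  fm2 <- fm_mid()
  fm2$target[rows[plan$test_idx]] <- 0.123   # corrupt test targets
  m2 <- methboost(fm2, plan = plan, seed = 9)
  p1 <- as.numeric(predict(m1, methboost:::fm_subset(fm, rows[plan$test_idx])))
  p2 <- as.numeric(predict(m2, methboost:::fm_subset(fm, rows[plan$test_idx])))
  expect_identical(p1, p2)
})

test_that("importance ranks a planted perfect feature first", {
  fm <- fm_mid()
  fm$target <- fm$sample_average
  m <- methboost(fm, seed = 4)
  imp <- variable_importance(m)
  expect_equal(imp$feature[1], "sample_average")
  expect_true(all(imp$gain >= 0))
  expect_true(all(diff(imp$gain) <= 0))
})

test_that("a single-feature model holds all the gain", {
  m <- methboost(fm_mid(), features = "A", seed = 5)
  imp <- variable_importance(m)
  expect_equal(imp$gain[imp$feature == "sample_average"], 1)
})

test_that("multi-seed importance aggregation equals the summed-gain oracle", {
  fms <- fm_mid()
  models <- lapply(1:3, function(s) methboost(fms, seed = s))
  agg <- variable_importance(models)
  feats <- sort(models[[1]]$feature_names)
  total <- setNames(rep(0, length(feats)), feats)
  for (m in models)
    total[names(m$importance)] <- total[names(m$importance)] + m$importance
  oracle_ranked <- names(total)[order(-total, names(total), method = "radix")]
  expect_identical(agg$feature, oracle_ranked)
  expect_equal(agg$gain, unname(total[oracle_ranked]))
})

test_that("balanced decile sampling equalizes occupied deciles", {
  # two occupied deciles sized 900 and 100 -> equal expected draws
  fm <- structure(
    data.frame(target = c(runif(900, 0, 0.1), runif(100, 0.9, 1.0)),
               trainable = TRUE),
    class = c("feature_matrix", "data.frame"), feature_names = character(0))
  idx <- balanced_decile_sample(fm, 200, seed = 1)
  n_low <- sum(fm$target[idx] < 0.5)
  expect_equal(n_low, 100L)                     # quotas equalize exactly
  expect_error(balanced_decile_sample(fm, 0, seed = 1), "positive")
  # bimodal targets: occupied deciles that can fill their quota do so
  fm2 <- fm_mid()
  n_draw <- 500L
  idx2 <- balanced_decile_sample(fm2, n_draw, seed = 2)
  expect_false(anyDuplicated(idx2) > 0)
  dec_all <- pmin(floor(fm2$target[fm2$trainable & !is.na(fm2$target)] * 10), 9)
  occupied <- sort(unique(dec_all))
  quota <- n_draw / length(occupied)
  dec <- pmin(floor(fm2$target[idx2] * 10), 9)
  counts <- table(factor(dec, levels = occupied))
  sizes <- table(factor(dec_all, levels = occupied))
  roomy <- sizes >= 2 * quota
  expect_true(all(abs(counts[roomy] - quota) <= quota))
  # a balanced draw is far flatter than the raw decile distribution
  expect_lt(max(counts) / max(1, min(counts)),
            max(sizes) / max(1, min(sizes)))
})

test_that("the repeated benchmark is deterministic and aggregates correctly", {
  fm <- fm_mid()
  r1 <- repeated_benchmark(fm, c(800, 300, 300), n_repeats = 2, base_seed = 5)
  r2 <- repeated_benchmark(fm, c(800, 300, 300), n_repeats = 2, base_seed = 5)
  expect_identical(r1$per_seed, r2$per_seed)
  expect_equal(r1$aggregate$mean[r1$aggregate$metric == "rmse_all"],
               mean(r1$per_seed$rmse_all))
  expect_true(all(r1$aggregate$sd >= 0))
  single <- repeated_benchmark(fm, c(800, 300, 300), n_repeats = 1,
                               base_seed = 5)
  expect_equal(single$aggregate$sd, rep(0, nrow(single$aggregate)))
  expect_identical(single$per_seed$rmse_all, r1$per_seed$rmse_all[1])
})

test_that("a model round-trips through its serialized form", {
  m <- model_mid()
  f <- withr::local_tempfile(fileext = ".json")
  write_methboost(m, f)
  m2 <- read_methboost(f)
  fm <- fm_mid()
  expect_equal(as.numeric(predict(m2, fm)), as.numeric(predict(m, fm)),
               tolerance = 1e-12)
  expect_identical(m2$feature_names, m$feature_names)
})

test_that("the random forest backend satisfies the same contract", {
  skip_if_not_installed("ranger")
  fm <- fm_mid()
  m <- methboost(fm, features = c("A", "N"), backend = "ranger", seed = 6)
  pred <- predict(m, methboost:::fm_subset(fm, which(fm$trainable)[1:200]))
  expect_true(all(pred >= 0 & pred <= 1))
  imp <- variable_importance(m)
  expect_setequal(imp$feature, c("sample_average", "beta_up", "beta_down",
                                 "dist_up", "dist_down"))
})
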