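#' Pinned gradient-boosting hyperparameters
#'
#' The defaults of the boosting backend, pinned explicitly so a fitted
#' model records exactly what it used rather than inheriting library
#' defaults that drift across versions.
#'
#' @param ... overrides, e.g. `max_depth = 4`.
#' @return named list of hyperparameters.
#' @export
methboost_params <- function(...) {
  p <- list(eta = 0.3, gamma = 0, max_depth = 6, min_child_weight = 1,
            subsample = 1, colsample_bytree = 1, lambda = 1, alpha = 0,
            objective = "reg:squarederror", nthread = 1)
  utils::modifyList(p, list(...))
}

#' Random train/validation/test split plan
#'
#' Uniform sampling without replacement into three disjoint index sets,
#' fully reproducible from the seed.  When the requested total exceeds the
#' number of eligible rows, sizes are scaled down proportionally only if
#' `scale = TRUE` (with a warning); the default is an error.
#'
#' @param n_eligible number of rows available.
#' @param sizes integer vector `c(train, val, test)`, all positive.
#' @param seed integer seed.
#' @param scale scale sizes down proportionally instead of erroring.
#' @return a `split_plan` list with `train_idx`, `val_idx`, `test_idx`,
#'   `seed`.
#' @export
make_split <- function(n_eligible, sizes, seed, scale = FALSE) {
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L || any(sizes <= 0L))
    stop("sizes must be three positive integers (train, val, test)")
  total <- sum(sizes)
  if (total > n_eligible) {
    if (!scale)
      stop(sprintf("requested %d rows but only %d eligible", total, n_eligible))
    sizes <- pmax(1L, as.integer(floor(sizes * n_eligible / total)))
    warning(sprintf("split sizes scaled down to %s to fit %d rows",
                    paste(sizes, collapse = "/"), n_eligible))
    total <- sum(sizes)
  }
  set.seed(seed)
  picked <- sample.int(n_eligible, total, replace = FALSE)
  structure(list(train_idx = picked[seq_len(sizes[1L])],
                 val_idx = picked[sizes[1L] + seq_len(sizes[2L])],
                 test_idx = picked[sizes[1L] + sizes[2L] + seq_len(sizes[3L])],
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Fit a gradient-boosted methylation imputation model
#'
#' The central fitting function: regression trees on continuous beta
#' targets in `[0, 1]`, trained on the plan's training rows with the
#' validation rows used for early stopping on RMSE.  The default backend
#' is gradient boosting; a random forest backend (package `ranger`) mirrors
#' the classical comparison and satisfies the same fit/predict/importance
#' contract.
#'
#' @param matrix a [assemble_matrix()] feature matrix.
#' @param plan a [make_split()] plan over the trainable rows of `matrix`;
#'   NULL fits on all trainable rows with a 90/10 train/validation split
#'   drawn with `seed`.
#' @param features optional subset of feature columns (names or group
#'   letters); default all features of the matrix.
#' @param backend `"xgboost"` or `"ranger"`.
#' @param params hyperparameters from [methboost_params()] (ignored by the
#'   ranger backend, which uses its own pinned set).
#' @param nrounds maximum boosting rounds (default 150).
#' @param early_stopping_rounds early-stopping patience on validation RMSE.
#' @param seed integer seed controlling backend randomness (and the
#'   default split when `plan` is NULL).
#' @param verbose print backend progress.
#' @return an object of class `"methboost"` with elements `fit`, `backend`,
#'   `feature_names`, `params`, `best_iteration`, `importance` and the
#'   evaluation context needed by its methods.
#' @export
methboost <- function(matrix, plan = NULL, features = NULL,
                      backend = c("xgboost", "ranger"),
                      params = methboost_params(), nrounds = 150L,
                      early_stopping_rounds = 10L, seed = 1L,
                      verbose = FALSE) {
  backend <- match.arg(backend)
  stopifnot(inherits(matrix, "feature_matrix"))
  feature_names <- resolve_features(matrix, features)
  trainable_rows <- which(matrix$trainable)
  if (length(trainable_rows) < 10L)
    stop("fewer than 10 trainable rows")
  if (is.null(plan)) {
    n <- length(trainable_rows)
    n_val <- max(1L, floor(n / 10))
    plan <- make_split(n, c(n - 2L * n_val, n_val, n_val), seed = seed)
  }
  tr <- trainable_rows[plan$train_idx]
  va <- trainable_rows[plan$val_idx]
  y_tr <- matrix$target[tr]
  y_va <- matrix$target[va]
  if (anyNA(y_tr) || anyNA(y_va))
    stop("undefined target beta in training/validation rows")
  if (any(y_tr < 0 | y_tr > 1)) stop("targets must lie in [0, 1]")
  x_tr <- as.matrix(matrix[tr, feature_names, drop = FALSE])
  x_va <- as.matrix(matrix[va, feature_names, drop = FALSE])
  finite_ok <- function(x) all(is.finite(x) | is.na(x))
  if (!finite_ok(x_tr) || !finite_ok(x_va))
    stop("non-finite feature values (other than NA) in the matrix")

  if (backend == "xgboost") {
    set.seed(seed)
    dtr <- xgboost::xgb.DMatrix(x_tr, label = y_tr)
    dva <- xgboost::xgb.DMatrix(x_va, label = y_va)
    fit <- xgboost::xgb.train(params = params, data = dtr,
                              nrounds = as.integer(nrounds),
                              evals = list(val = dva),
                              early_stopping_rounds = early_stopping_rounds,
                              verbose = if (verbose) 1L else 0L)
    best_iter <- tryCatch(xgboost::xgb.attr(fit, "best_iteration"),
                          error = function(e) NULL)
    imp <- xgb_gain_importance(fit, feature_names)
  } else {
    if (!requireNamespace("ranger", quietly = TRUE))
      stop("the ranger backend requires the 'ranger' package")
    df_tr <- as.data.frame(x_tr)
    df_tr$..target <- y_tr
    fit <- ranger::ranger(dependent.variable.name = "..target", data = df_tr,
                          num.trees = 500L, importance = "impurity",
                          seed = seed, num.threads = 1L,
                          verbose = isTRUE(verbose))
    best_iter <- NULL
    imp <- sort_importance(ranger::importance(fit))
  }
  structure(list(fit = fit, backend = backend,
                 feature_names = feature_names,
                 feature_set = attr(matrix, "feature_set"),
                 params = if (backend == "xgboost") params else
                   list(num.trees = 500L, importance = "impurity"),
                 nrounds = as.integer(nrounds),
                 best_iteration = best_iter,
                 importance = imp, seed = as.integer(seed),
                 n_train = length(tr), n_val = length(va),
                 target_sample = attr(matrix, "target_sample")),
            class = "methboost")
}

resolve_features <- function(matrix, features) {
  all_feats <- attr(matrix, "feature_names")
  if (is.null(features)) return(all_feats)
  groups <- attr(matrix, "feature_group_of")
  if (all(features %in% names(feature_groups()))) {
    out <- all_feats[groups[all_feats] %in% features]
  } else {
    bad <- setdiff(features, all_feats)
    if (length(bad) > 0L)
      stop("unknown feature(s): ", paste(bad, collapse = ", "))
    out <- features
  }
  if (length(out) == 0L) stop("no features selected")
  out
}

# total gain per feature (normalized to sum 1) from the booster's tree
# dump: loss reduction summed over every split using the feature
xgb_gain_importance <- function(fit, feature_names) {
  gain <- stats::setNames(rep(0, length(feature_names)), feature_names)
  dt <- tryCatch(xgboost::xgb.model.dt.tree(model = fit),
                 error = function(e) NULL)
  if (!is.null(dt) && nrow(dt) > 0L) {
    splits <- dt[!is.na(dt$Split) & dt$Feature %in% feature_names, ,
                 drop = FALSE]
    if (nrow(splits) > 0L) {
      agg <- tapply(splits$Gain, splits$Feature, sum)
      gain[names(agg)] <- agg
      if (sum(gain) > 0) gain <- gain / sum(gain)
    }
  }
  sort_importance(gain)
}

# descending by gain, ties broken lexicographically by feature name
sort_importance <- function(gain) {
  gain[order(-gain, names(gain), method = "radix")]
}

#' @export
print.methboost <- function(x, ...) {
  cat(sprintf("methboost model (%s backend)\n", x$backend))
  cat(sprintf("  trained on %d CpGs (%d validation) from sample %s\n",
              x$n_train, x$n_val, x$target_sample %||% "?"))
  cat(sprintf("  %d features [groups %s]\n", length(x$feature_names),
              paste(x$feature_set, collapse = ",")))
  top <- utils::head(x$importance, 5L)
  cat("  top features by gain: ",
      paste(sprintf("%s (%.3f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.methboost <- function(object, ...) {
  cat(sprintf("Gradient-boosted methylation imputation model (%s)\n\n",
              object$backend))
  cat("Hyperparameters:\n")
  for (nm in names(object$params))
    cat(sprintf("  %s = %s\n", nm, format(object$params[[nm]])))
  if (!is.null(object$best_iteration))
    cat(sprintf("Best iteration (early stopping on validation RMSE): %s\n",
                object$best_iteration))
  cat("\nVariable importance (gain):\n")
  imp <- variable_importance(object)
  print(utils::head(imp, 10L), row.names = FALSE)
  invisible(imp)
}

#' Predict beta values
#'
#' Raw backend outputs clipped to `[0, 1]` (count of clipped predictions in
#' the `n_clipped` attribute).
#'
#' @param object a fitted [methboost()] model.
#' @param newdata a `feature_matrix` (or data.frame containing the model's
#'   feature columns).
#' @param clip clip predictions into `[0, 1]` (default TRUE).
#' @param ... unused.
#' @return numeric vector of predicted betas.
#' @export
predict.methboost <- function(object, newdata, clip = TRUE, ...) {
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols) > 0L)
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  p <- if (object$backend == "xgboost") {
    stats::predict(object$fit, xgboost::xgb.DMatrix(x))
  } else {
    stats::predict(object$fit, data = as.data.frame(x),
                   num.threads = 1L)$predictions
  }
  n_clipped <- sum(p < 0 | p > 1)
  if (clip) p <- pmin(pmax(p, 0), 1)
  attr(p, "n_clipped") <- n_clipped
  p
}

#' Residuals of a fitted model on its training matrix
#' @param object a [methboost()] model.
#' @param matrix the feature matrix it was fitted on.
#' @param ... unused.
#' @return observed minus predicted beta on trainable rows.
#' @export
residuals.methboost <- function(object, matrix, ...) {
  rows <- which(matrix$trainable)
  matrix$target[rows] - as.numeric(predict(object, fm_subset(matrix, rows)))
}

#' Ranked variable importance
#'
#' Features ranked by total gain (loss reduction summed over all splits
#' using the feature); ties broken lexicographically for determinism.
#'
#' @param model a fitted [methboost()] model, or a list of fitted models
#'   whose gains are aggregated by summation before ranking.
#' @return data.frame `feature, gain, rank` in descending gain order.
#' @export
variable_importance <- function(model) {
  if (inherits(model, "methboost")) models <- list(model)
  else if (is.list(model) && all(vapply(model, inherits, TRUE, "methboost")))
    models <- model
  else stop("expected a fitted methboost model (or list of them)")
  feats <- models[[1L]]$feature_names
  total <- stats::setNames(rep(0, length(feats)), feats)
  for (m in models) {
    if (!identical(sort(names(m$importance)), sort(feats)))
      stop("models have differing feature sets")
    total[names(m$importance)] <- total[names(m$importance)] + m$importance
  }
  total <- sort_importance(total)
  data.frame(feature = names(total), gain = unname(total),
             rank = seq_along(total), stringsAsFactors = FALSE)
}

#' Importance bar plot
#' @param x a fitted [methboost()] model.
#' @param top_n number of features shown (default 15).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.methboost <- function(x, top_n = 15L, ...) {
  imp <- utils::head(variable_importance(x), top_n)
  graphics::barplot(rev(imp$gain), names.arg = rev(imp$feature), horiz = TRUE,
                    las = 1, xlab = "total gain", ...)
  invisible(imp)
}

#' Inverse-decile-frequency balanced training sample
#'
#' Draws rows with probability inversely proportional to the size of their
#' target-beta decile (`[0,0.1), ..., [0.9,1]`), flattening the bimodal
#' beta distribution; empty deciles redistribute their mass proportionally.
#'
#' @param matrix a `feature_matrix`; only trainable rows are drawn from.
#' @param n number of rows to draw (without replacement; a decile smaller
#'   than its quota contributes all its rows and the shortfall is
#'   redistributed over the remaining deciles).
#' @param seed integer seed.
#' @return integer vector of row indices into `matrix`.
#' @export
balanced_decile_sample <- function(matrix, n, seed) {
  if (n <= 0L) stop("n must be positive")
  rows <- which(matrix$trainable & !is.na(matrix$target))
  n <- min(n, length(rows))
  y <- matrix$target[rows]
  dec <- pmin(floor(y * 10), 9L)         # [0.9, 1] is the top decile
  by_dec <- split(rows, dec)
  size <- lengths(by_dec)
  # equal quotas over occupied deciles; iterative redistribution when a
  # decile cannot fill its quota
  quota <- stats::setNames(rep(0L, length(by_dec)), names(by_dec))
  remaining <- n
  open <- names(by_dec)
  while (remaining > 0L && length(open) > 0L) {
    share <- ceiling(remaining / length(open))
    for (d in open) {
      add <- min(share, size[d] - quota[d], remaining)
      quota[d] <- quota[d] + add
      remaining <- remaining - add
      if (remaining == 0L) break
    }
    open <- names(by_dec)[quota < size[names(by_dec)]]
  }
  set.seed(seed)
  picked <- unlist(lapply(names(by_dec), function(d) {
    if (quota[d] == 0L) return(integer(0))
    if (quota[d] >= size[d]) by_dec[[d]]
    else sample(by_dec[[d]], quota[d])
  }), use.names = FALSE)
  sort(picked)
}

#' Repeated random-subsampling benchmark
#'
#' For each of `n_repeats` seeds: draw disjoint train/validation/test sets,
#' fit, predict the held-out test rows, and score.  Reports per-seed
#' metrics and their mean and standard deviation.
#'
#' @param matrix a `feature_matrix`.
#' @param sizes `c(train, val, test)` row counts over trainable rows.
#' @param n_repeats number of random seeds (default 10).
#' @param base_seed first seed; repeat `i` uses `base_seed + i - 1`.
#' @param features feature subset (names or group letters), as in
#'   [methboost()].
#' @param backend,params,nrounds,early_stopping_rounds passed to
#'   [methboost()].
#' @param balanced draw the training rows with [balanced_decile_sample()]
#'   instead of uniformly (validation/test stay uniform).
#' @return a `benchmark_report`: list with `per_seed` (data.frame) and
#'   `aggregate` (mean/sd per metric).
#' @export
repeated_benchmark <- function(matrix, sizes, n_repeats = 10L, base_seed = 1L,
                               features = NULL, backend = "xgboost",
                               params = methboost_params(), nrounds = 150L,
                               early_stopping_rounds = 10L,
                               balanced = FALSE) {
  trainable_rows <- which(matrix$trainable)
  n <- length(trainable_rows)
  scale <- sum(sizes) > n
  rows_list <- list()
  for (i in seq_len(n_repeats)) {
    seed <- as.integer(base_seed) + i - 1L
    plan <- make_split(n, sizes, seed = seed, scale = scale)
    if (balanced) {
      # replace the uniform training draw by a decile-balanced draw over
      # trainable rows not used for validation/testing
      held <- trainable_rows[c(plan$val_idx, plan$test_idx)]
      sub <- fm_subset(matrix, setdiff(seq_len(nrow(matrix)), held))
      bal_rows_local <- balanced_decile_sample(sub, length(plan$train_idx),
                                               seed = seed)
      keep <- setdiff(seq_len(nrow(matrix)), held)
      train_global <- keep[bal_rows_local]
    } else {
      train_global <- trainable_rows[plan$train_idx]
    }
    rows_list[[i]] <- list(seed = seed,
                           train = train_global,
                           val = trainable_rows[plan$val_idx],
                           test = trainable_rows[plan$test_idx])
  }
  per_seed <- lapply(rows_list, function(r) {
    sub <- fm_subset(matrix, c(r$train, r$val))
    n_tr <- length(r$train)
    plan <- list(train_idx = seq_len(n_tr),
                 val_idx = n_tr + seq_along(r$val),
                 test_idx = integer(0), seed = r$seed)
    class(plan) <- "split_plan"
    sub$trainable <- TRUE
    model <- methboost(sub, plan = plan, features = features,
                       backend = backend, params = params, nrounds = nrounds,
                       early_stopping_rounds = early_stopping_rounds,
                       seed = r$seed)
    test <- fm_subset(matrix, r$test)
    pred <- as.numeric(predict(model, test))
    ms <- metric_set(pred, test$target,
                     sample_avg = if ("sample_average" %in% names(test))
                       test$sample_average else test$target)
    data.frame(seed = r$seed, rmse_all = ms$rmse_all,
               rmse_intermediate = ms$rmse_intermediate, auroc = ms$auroc,
               auprc = ms$auprc, accuracy = ms$accuracy)
  })
  per_seed <- do.call(rbind, per_seed)
  metrics <- setdiff(names(per_seed), "seed")
  aggregate <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_seed[[m]]), 0),
    sd = vapply(metrics, function(m)
      if (nrow(per_seed) > 1L) stats::sd(per_seed[[m]]) else 0, 0),
    row.names = NULL)
  structure(list(per_seed = per_seed, aggregate = aggregate,
                 sizes = sizes, backend = backend,
                 features = features %||% "all"),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark_report: %d repeat(s), %s backend, features: %s\n",
              nrow(x$per_seed), x$backend,
              paste(x$features, collapse = ",")))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-18s %.5f +/- %.5f\n", agg$metric[i], agg$mean[i],
                agg$sd[i]))
  invisible(x)
}

#' Save / load a fitted model
#'
#' Self-describing JSON: backend name, feature order, hyperparameters and
#' importance, plus the base64-encoded backend-native payload (gradient
#' boosting backend only).
#'
#' @param model a fitted [methboost()] model.
#' @param path file path.
#' @return `path` invisibly (`write_methboost`); a `methboost` model
#'   (`read_methboost`).
#' @export
write_methboost <- function(model, path) {
  stopifnot(inherits(model, "methboost"))
  if (model$backend != "xgboost")
    stop("serialization is implemented for the gradient boosting backend")
  raw <- xgboost::xgb.save.raw(model$fit)
  obj <- list(backend = model$backend, feature_names = model$feature_names,
              feature_set = model$feature_set, params = model$params,
              nrounds = model$nrounds, seed = model$seed,
              importance = as.list(model$importance),
              payload = jsonlite::base64_enc(raw))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_methboost
#' @export
read_methboost <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- xgboost::xgb.load.raw(jsonlite::base64_dec(obj$payload))
  structure(list(fit = fit, backend = obj$backend,
                 feature_names = obj$feature_names,
                 feature_set = obj$feature_set,
                 params = obj$params, nrounds = obj$nrounds,
                 best_iteration = NULL,
                 importance = unlist(obj$importance), seed = obj$seed,
                 n_train = NA_integer_, n_val = NA_integer_,
                 target_sample = NULL),
            class = "methboost")
}
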