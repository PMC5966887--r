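#' Root-mean-squared error
#'
#' @param pred,truth equal-length beta vectors in `[0, 1]`.
#' @return `sqrt(mean((pred - truth)^2))`.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) == 0L) stop("empty input")
  sqrt(mean((pred - truth)^2))
}

#' Intermediate-methylation mask
#'
#' TRUE where the cross-sample average beta lies in `[lo, hi]`, both ends
#' inclusive; undefined averages give FALSE.  The mask is computed from
#' the sample average, never from the target beta, so that the
#' intermediate stratum does not depend on the value being predicted.
#'
#' @param sample_avg cross-sample average betas (NA allowed).
#' @param lo,hi inclusive interval bounds (defaults 0.20, 0.80).
#' @return logical vector.
#' @export
intermediate_mask <- function(sample_avg, lo = 0.20, hi = 0.80) {
  if (lo > hi) stop("lo > hi")
  !is.na(sample_avg) & sample_avg >= lo & sample_avg <= hi
}

#' Binary classification metrics on continuous predictions
#'
#' Truth betas are binarized at `threshold` (methylated iff beta >=
#' threshold); predictions serve as continuous scores for AUROC (midrank
#' tie handling) and AUPRC (precision-recall step integration), and are
#' thresholded for accuracy.  With single-class truth AUROC and AUPRC are
#' NA; accuracy is still computed.
#'
#' @param pred continuous scores in `[0, 1]`.
#' @param truth beta values in `[0, 1]`.
#' @param threshold binarization threshold (default 0.5; ties count as
#'   methylated).
#' @return list `auroc`, `auprc`, `accuracy`.
#' @export
classification_metrics <- function(pred, truth, threshold = 0.5) {
  if (length(pred) == 0L || length(pred) != length(truth))
    stop("empty input or length mismatch")
  lab <- truth >= threshold
  acc <- mean((pred >= threshold) == lab)
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L)
    return(list(auroc = NA_real_, auprc = NA_real_, accuracy = acc))
  r <- rank(pred)                        # midranks for ties
  auroc <- (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  auprc <- auprc_step(pred, lab)
  list(auroc = auroc, auprc = auprc, accuracy = acc)
}

# precision-recall step integration: at each distinct score threshold
# (descending) add precision * recall-increment
auprc_step <- function(scores, lab) {
  o <- order(scores, decreasing = TRUE)
  lab <- lab[o]; scores <- scores[o]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  # evaluate only at the last index of each tied score block
  last <- c(scores[-1L] != scores[-length(scores)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  n_pos <- sum(lab)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Full metric set
#'
#' @param pred,truth beta vectors; pairs with an NA member are dropped.
#' @param sample_avg cross-sample averages defining the intermediate
#'   stratum (see [intermediate_mask()]).
#' @param lo,hi intermediate interval (0.20, 0.80 inclusive).
#' @param threshold binarization threshold for classification metrics.
#' @return a `metric_set` list: `rmse_all`, `rmse_intermediate`, `auroc`,
#'   `auprc`, `accuracy`, `n_all`, `n_intermediate`.
#' @export
metric_set <- function(pred, truth, sample_avg, lo = 0.20, hi = 0.80,
                       threshold = 0.5) {
  keep <- !is.na(pred) & !is.na(truth)
  pred <- pred[keep]; truth <- truth[keep]; sample_avg <- sample_avg[keep]
  mask <- intermediate_mask(sample_avg, lo, hi)
  cls <- classification_metrics(pred, truth, threshold)
  structure(list(
    rmse_all = rmse(pred, truth),
    rmse_intermediate = if (any(mask)) rmse(pred[mask], truth[mask]) else NA_real_,
    auroc = cls$auroc, auprc = cls$auprc, accuracy = cls$accuracy,
    n_all = length(pred), n_intermediate = sum(mask)),
    class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(paste0("RMSE (all) %.5f | RMSE (int.) %.5f | AUROC %.5f | ",
                     "AUPRC %.5f | accuracy %.5f  [n=%d, int=%d]\n"),
              x$rmse_all, x$rmse_intermediate, x$auroc, x$auprc, x$accuracy,
              x$n_all, x$n_intermediate))
  invisible(x)
}

#' Absolute error profile by distance to the nearest informative neighbour
#'
#' Bins `|pred - truth|` by the distance to the nearest non-missing
#' neighbouring CpG (`min(dist_up, dist_down)`), stratified by chromatin
#' state.
#'
#' @param pred,truth beta vectors.
#' @param dist_to_nearest bp distances (one per CpG).
#' @param state_labels chromatin state per CpG (NA allowed; grouped as
#'   `"unannotated"`).
#' @param bin_width bin width in bp (default 50).
#' @param max_dist distances beyond this are pooled in the top bin.
#' @return data.frame `state, bin_start, bin_end, n, mean_abs_error,
#'   q25, q50, q75`.
#' @export
error_by_distance <- function(pred, truth, dist_to_nearest,
                              state_labels = NULL, bin_width = 50L,
                              max_dist = 1000L) {
  if (bin_width <= 0L) stop("bin_width must be positive")
  n <- length(pred)
  stopifnot(length(truth) == n, length(dist_to_nearest) == n)
  if (is.null(state_labels)) state_labels <- rep("all", n)
  state_labels[is.na(state_labels)] <- "unannotated"
  err <- abs(pred - truth)
  bin <- pmin(floor(dist_to_nearest / bin_width),
              floor((max_dist - 1) / bin_width))
  key <- split(err, list(state = state_labels, bin = bin), drop = TRUE)
  parts <- strsplit(names(key), ".", fixed = TRUE)
  out <- data.frame(
    state = vapply(parts, `[[`, "", 1L),
    bin_start = as.integer(vapply(parts, `[[`, "", 2L)) * bin_width,
    stringsAsFactors = FALSE)
  out$bin_end <- out$bin_start + bin_width
  out$n <- vapply(key, length, 0L)
  out$mean_abs_error <- vapply(key, mean, 0)
  q <- t(vapply(key, stats::quantile, c(0, 0, 0), probs = c(.25, .5, .75)))
  out$q25 <- q[, 1L]; out$q50 <- q[, 2L]; out$q75 <- q[, 3L]
  out <- out[order(out$state, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
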