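#' Missingness by chromatin state
#'
#' Per-state count of missing (depth < 10) CpGs normalized by the total
#' number of CpGs in that state.
#'
#' @param table a [methyl_table()].
#' @param state_track data.frame `chrom,start,end,label` (non-overlapping).
#' @return data.frame `state, n_missing, n_total, fraction` (fraction NA
#'   for states containing zero CpGs).
#' @export
missingness_by_state <- function(table, state_track) {
  stopifnot(inherits(table, "methyl_table"))
  bundle <- annotation_bundle(state_track = state_track)
  st <- state_at(bundle, table$chrom, table$pos)
  st[is.na(st)] <- "unannotated"
  states <- union(bundle$states, unique(st))
  n_total <- vapply(states, function(s) sum(st == s), 0L)
  n_missing <- vapply(states, function(s) sum(st == s & table$is_missing), 0L)
  data.frame(state = states, n_missing = n_missing, n_total = n_total,
             fraction = ifelse(n_total > 0L, n_missing / n_total, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise beta differences within chromatin-state runs
#'
#' Enumerates maximal runs of consecutive CpGs sharing one chromatin state
#' (and chromosome), samples runs uniformly, and within each sampled run
#' emits all CpG pairs with span at most `max_span` until the per-state
#' pair budget is met.  Pairs never straddle two states or chromosomes;
#' with `regions` given, pairs are additionally confined to single regions
#' (used for the high-variance block analysis).
#'
#' @param mean_betas data.frame `chrom, pos, beta` of per-CpG cohort-mean
#'   betas (CpGs with undefined means excluded upstream).
#' @param state_track chromatin-state BED data.frame.
#' @param n_pairs per-state pair budget (default 2e4).
#' @param seed sampling seed.
#' @param max_span maximum pair span in bp (default 1000).
#' @param regions optional data.frame `chrom,start,end`; only pairs lying
#'   entirely inside one region are emitted.
#' @return data.frame `state, distance, abs_diff`.
#' @export
pairwise_differences <- function(mean_betas, state_track, n_pairs = 2e4,
                                 seed = 1L, max_span = 1000L,
                                 regions = NULL) {
  stopifnot(all(c("chrom", "pos", "beta") %in% names(mean_betas)))
  mb <- mean_betas[!is.na(mean_betas$beta), , drop = FALSE]
  mb <- mb[order(mb$chrom, mb$pos), , drop = FALSE]
  bundle <- annotation_bundle(state_track = state_track)
  st <- state_at(bundle, mb$chrom, mb$pos)
  region_id <- rep(0L, nrow(mb))
  if (!is.null(regions) && nrow(regions) > 0L) {
    region_id <- rep(NA_integer_, nrow(mb))
    for (cc in unique(mb$chrom)) {
      sel <- mb$chrom == cc
      r <- regions[regions$chrom == cc, , drop = FALSE]
      if (nrow(r) == 0L) next
      r <- r[order(r$start), , drop = FALSE]
      idx <- findInterval(mb$pos[sel], r$start)
      ok <- idx >= 1L & mb$pos[sel] < r$end[pmax(idx, 1L)]
      region_id[sel][ok] <- idx[ok]
    }
  }
  keep <- !is.na(st) & !is.na(region_id)
  mb <- mb[keep, , drop = FALSE]; st <- st[keep]; region_id <- region_id[keep]
  if (nrow(mb) == 0L)
    return(data.frame(state = character(0), distance = integer(0),
                      abs_diff = numeric(0)))
  # maximal runs of constant (chrom, state, region)
  run_key <- paste(mb$chrom, st, region_id)
  run_id <- cumsum(c(TRUE, run_key[-1L] != run_key[-length(run_key)]))
  runs <- split(seq_len(nrow(mb)), run_id)
  runs <- runs[vapply(runs, length, 0L) >= 2L]
  run_state <- vapply(runs, function(i) st[i[1L]], "")
  set.seed(seed)
  out <- list()
  for (s in sort(unique(run_state))) {
    rs <- runs[run_state == s]
    order_rs <- sample(length(rs))      # uniform run order
    got <- 0L; acc <- list(); k <- 0L
    for (ri in order_rs) {
      i <- rs[[ri]]
      pos <- mb$pos[i]; beta <- mb$beta[i]
      pr <- run_pairs(pos, beta, max_span)
      if (nrow(pr) == 0L) next
      k <- k + 1L
      acc[[k]] <- pr
      got <- got + nrow(pr)
      if (got >= n_pairs) break
    }
    if (k > 0L) {
      d <- do.call(rbind, acc)
      if (nrow(d) > n_pairs) d <- d[seq_len(n_pairs), , drop = FALSE]
      d$state <- s
      out[[s]] <- d
    }
  }
  if (length(out) == 0L)
    return(data.frame(state = character(0), distance = integer(0),
                      abs_diff = numeric(0)))
  res <- do.call(rbind, unname(out))
  res[, c("state", "distance", "abs_diff")]
}

# all within-run pairs with span <= max_span
run_pairs <- function(pos, beta, max_span) {
  n <- length(pos)
  ii <- jj <- integer(0)
  for (a in seq_len(n - 1L)) {
    b <- a + 1L
    while (b <= n && pos[b] - pos[a] <= max_span) b <- b + 1L
    if (b - 1L >= a + 1L) {
      ii <- c(ii, rep(a, b - 1L - a))
      jj <- c(jj, (a + 1L):(b - 1L))
    }
  }
  data.frame(distance = pos[jj] - pos[ii], abs_diff = abs(beta[jj] - beta[ii]))
}

#' Find blocks of consecutive high across-tissue-variance CpGs
#'
#' Per-CpG beta variance is computed across all samples of all supplied
#' cohorts, over samples with a non-missing value (depth >= 10); CpGs with
#' fewer than `min_nonmissing` such samples are not considered.  The
#' variance threshold is the `variance_quantile` sample quantile (type 7)
#' over considered CpGs; qualifying CpGs lie strictly above it.  Blocks
#' are maximal runs of consecutive qualifying CpGs (adjacent in the
#' genome-wide CpG index) with at least `min_block` members.
#'
#' @param cohorts list of [cohort_set()] objects (>= 2 tissues), or a
#'   single `cohort_set`.
#' @param min_nonmissing minimum non-missing samples per CpG (default 20).
#' @param variance_quantile quantile defining "high" variance (default
#'   0.75, the third quartile).
#' @param min_block minimum CpGs per block (default 2).
#' @return data.frame `chrom, start, end, cpg_count, mean_variance`
#'   (half-open spans covering first to last member dyad); attribute
#'   `member_index` holds the data.frame `chrom,pos` of member CpGs and
#'   `threshold` the variance cutoff.
#' @export
find_high_variance_blocks <- function(cohorts, min_nonmissing = 20L,
                                      variance_quantile = 0.75,
                                      min_block = 2L) {
  if (inherits(cohorts, "cohort_set")) cohorts <- list(cohorts)
  stopifnot(length(cohorts) >= 1L,
            all(vapply(cohorts, inherits, TRUE, "cohort_set")))
  n_samples <- sum(vapply(cohorts, function(co) ncol(co$beta), 0L))
  if (min_nonmissing > n_samples)
    stop(sprintf("min_nonmissing (%d) exceeds total sample count (%d)",
                 min_nonmissing, n_samples))
  # union CpG index across cohorts
  keys <- unique(do.call(rbind, lapply(cohorts, function(co) co$index)))
  keys <- keys[order(keys$chrom, keys$pos), , drop = FALSE]
  rownames(keys) <- NULL
  key_str <- paste(keys$chrom, keys$pos)
  beta <- matrix(NA_real_, nrow(keys), 0L)
  for (co in cohorts) {
    b <- co$beta
    b[co$depth < 10L] <- NA_real_       # non-missing means depth >= 10
    m <- matrix(NA_real_, nrow(keys), ncol(b),
                dimnames = list(NULL, colnames(b)))
    m[match(paste(co$index$chrom, co$index$pos), key_str), ] <- b
    beta <- cbind(beta, m)
  }
  nn <- rowSums(!is.na(beta))
  considered <- nn >= min_nonmissing
  v <- rep(NA_real_, nrow(keys))
  v[considered] <- apply(beta[considered, , drop = FALSE], 1L,
                         stats::var, na.rm = TRUE)
  thr <- stats::quantile(v[considered], probs = variance_quantile,
                         type = 7, na.rm = TRUE, names = FALSE)
  qual <- considered & !is.na(v) & v > thr
  # maximal runs of consecutive qualifying CpGs in the genome-wide index,
  # never crossing a chromosome
  blocks <- list()
  members <- integer(0)
  r <- rle(qual & TRUE)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  bi <- 0L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    i <- idx_start[k]:idx_end[k]
    # split at chromosome boundaries within the run
    for (piece in split(i, keys$chrom[i])) {
      piece <- sort(piece)
      if (length(piece) < min_block) next
      bi <- bi + 1L
      blocks[[bi]] <- data.frame(
        chrom = keys$chrom[piece[1L]],
        start = keys$pos[piece[1L]],
        end = keys$pos[piece[length(piece)]] + 2L,
        cpg_count = length(piece),
        mean_variance = mean(v[piece]),
        stringsAsFactors = FALSE)
      members <- c(members, piece)
    }
  }
  out <- if (bi > 0L) do.call(rbind, blocks)
  else data.frame(chrom = character(0), start = integer(0), end = integer(0),
                  cpg_count = integer(0), mean_variance = numeric(0))
  rownames(out) <- NULL
  structure(out, member_index = keys[sort(members), , drop = FALSE],
            threshold = thr, class = c("variance_blocks", "data.frame"))
}

#' WGBS-versus-reference discordance grid
#'
#' Joins the two beta estimates on shared positions, bins by WGBS
#' sequencing depth (width-5 bins `[5i, 5i+5)`) and by reference beta
#' (width-0.05 bins, the top bin right-closed to include 1.0), and
#' computes the root-mean-squared discordance per cell.
#'
#' @param primary data.frame `chrom, pos, beta, depth` (WGBS side).
#' @param reference data.frame `chrom, pos, beta` (array side).
#' @param depth_bin depth bin width (default 5).
#' @param beta_bin beta bin width (default 0.05).
#' @return a `discordance_grid` data.frame `depth_bin_start,
#'   beta_bin_start, n, rmsd`; attribute `n_joined` is the inner-join size.
#' @export
discordance_grid <- function(primary, reference, depth_bin = 5L,
                             beta_bin = 0.05) {
  stopifnot(all(c("chrom", "pos", "beta", "depth") %in% names(primary)),
            all(c("chrom", "pos", "beta") %in% names(reference)))
  i <- match(paste(primary$chrom, primary$pos),
             paste(reference$chrom, reference$pos))
  keep <- !is.na(i) & !is.na(primary$beta)
  if (!any(keep)) stop("no shared positions between primary and reference")
  pb <- primary$beta[keep]
  rb <- reference$beta[i[keep]]
  dp <- primary$depth[keep]
  db <- floor(dp / depth_bin) * depth_bin
  n_beta_bins <- round(1 / beta_bin)
  bb <- pmin(floor(rb / beta_bin), n_beta_bins - 1L) * beta_bin
  sq <- (pb - rb)^2
  key <- paste(db, signif(bb, 10))
  agg_n <- tapply(sq, key, length)
  agg_m <- tapply(sq, key, mean)
  parts <- strsplit(names(agg_n), " ", fixed = TRUE)
  out <- data.frame(
    depth_bin_start = as.numeric(vapply(parts, `[[`, "", 1L)),
    beta_bin_start = as.numeric(vapply(parts, `[[`, "", 2L)),
    n = as.integer(agg_n), rmsd = sqrt(as.numeric(agg_m)))
  out <- out[order(out$depth_bin_start, out$beta_bin_start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_joined = sum(keep), depth_bin = depth_bin,
            beta_bin = beta_bin, class = c("discordance_grid", "data.frame"))
}

#' Cellwise difference between two discordance grids
#'
#' `before - after` per cell (positive where imputation reduced the
#' discordance); cells occupied in only one grid are dropped.
#'
#' @param before,after [discordance_grid()] objects with identical binning.
#' @return data.frame `depth_bin_start, beta_bin_start, n_before, n_after,
#'   delta_rmsd`.
#' @export
grid_difference <- function(before, after) {
  stopifnot(inherits(before, "discordance_grid"),
            inherits(after, "discordance_grid"))
  if (!identical(attr(before, "depth_bin"), attr(after, "depth_bin")) ||
      !identical(attr(before, "beta_bin"), attr(after, "beta_bin")))
    stop("grids have different binning")
  kb <- paste(before$depth_bin_start, before$beta_bin_start)
  ka <- paste(after$depth_bin_start, after$beta_bin_start)
  common <- intersect(kb, ka)
  ib <- match(common, kb); ia <- match(common, ka)
  out <- data.frame(
    depth_bin_start = before$depth_bin_start[ib],
    beta_bin_start = before$beta_bin_start[ib],
    n_before = before$n[ib], n_after = after$n[ia],
    delta_rmsd = before$rmsd[ib] - after$rmsd[ia])
  out[order(out$depth_bin_start, out$beta_bin_start), , drop = FALSE]
}

#' Correlations among target beta and top-ranked features
#'
#' Pearson correlation matrix over the target beta and the given features
#' (typically the top-k by variable importance), in the given order.
#' Zero-variance features yield NA rows/columns.
#'
#' @param matrix a `feature_matrix`.
#' @param features feature names, e.g.
#'   `head(variable_importance(model)$feature, 30)`.
#' @return symmetric correlation matrix with `beta` first.
#' @export
feature_correlation_matrix <- function(matrix, features) {
  bad <- setdiff(features, attr(matrix, "feature_names"))
  if (length(bad) > 0L)
    stop("unknown feature(s): ", paste(bad, collapse = ", "))
  m <- cbind(beta = matrix$target,
             as.matrix(as.data.frame(matrix)[, features, drop = FALSE]))
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
}

#' Write a discordance grid (or grid difference) as tidy TSV
#' @param grid a `discordance_grid` or [grid_difference()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
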