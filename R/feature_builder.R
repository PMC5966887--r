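#' Assemble a multi-sample cohort
#'
#' A cohort is a set of at least three methylation tables from the same
#' tissue and disease group, aligned on the union of their CpG positions.
#' Beta and depth matrices over the union index support fast cross-sample
#' lookups (leave-one-out sample average, across-sample variance).
#'
#' @param tables list of [methyl_table()] objects (>= 3), distinct
#'   `sample_id`s, matching `tissue`/`disease_state`.
#' @return a `cohort_set`: list with `tables`, `index` (chrom/pos of the
#'   union), `beta` and `depth` matrices (CpG x sample).
#' @export
cohort_set <- function(tables) {
  if (length(tables) < 3L)
    stop("a cohort needs at least three samples")
  if (!all(vapply(tables, inherits, TRUE, "methyl_table")))
    stop("all elements must be methyl_table objects")
  ids <- vapply(tables, attr, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample_id in cohort")
  tis <- unique(vapply(tables, attr, "", "tissue"))
  dis <- unique(vapply(tables, attr, "", "disease_state"))
  if (length(tis) != 1L || length(dis) != 1L)
    stop("cohort samples must share tissue and disease_state")
  names(tables) <- ids
  keys <- unique(do.call(rbind, lapply(tables, function(t)
    data.frame(chrom = t$chrom, pos = t$pos, stringsAsFactors = FALSE))))
  keys <- keys[order(keys$chrom, keys$pos), , drop = FALSE]
  rownames(keys) <- NULL
  key_str <- paste(keys$chrom, keys$pos)
  n <- nrow(keys)
  beta <- matrix(NA_real_, n, length(tables), dimnames = list(NULL, ids))
  depth <- matrix(0L, n, length(tables), dimnames = list(NULL, ids))
  for (s in ids) {
    t <- tables[[s]]
    i <- match(paste(t$chrom, t$pos), key_str)
    beta[i, s] <- t$beta
    depth[i, s] <- t$n_total
  }
  structure(list(tables = tables, index = keys, beta = beta, depth = depth,
                 tissue = tis, disease_state = dis),
            class = "cohort_set")
}

#' @export
print.cohort_set <- function(x, ...) {
  cat(sprintf("cohort_set: %d samples (%s, %s), %d union CpGs\n",
              length(x$tables), x$tissue, x$disease_state, nrow(x$index)))
  invisible(x)
}

#' Nearest non-missing neighbour features
#'
#' For each CpG of a sample, the beta of the closest non-missing CpG at a
#' lower position (`beta_up`) and at a higher position (`beta_down`),
#' together with base-pair distances between dyad start positions.
#' Neighbours are searched within the same sample and never across a
#' chromosome boundary.  Rows lacking either neighbour get NA features and
#' `complete = FALSE`.
#'
#' @param table a sorted [methyl_table()].
#' @param target_index optional row indices; default all rows.
#' @return data.frame `beta_up, dist_up, beta_down, dist_down, complete`.
#' @export
neighbor_features <- function(table, target_index = NULL) {
  stopifnot(inherits(table, "methyl_table"))
  if (!identical(order(table$chrom, table$pos), seq_len(nrow(table))))
    stop("table must be sorted by (chrom, pos)")
  n <- nrow(table)
  beta_up <- beta_down <- rep(NA_real_, n)
  dist_up <- dist_down <- rep(NA_real_, n)
  for (cc in unique(table$chrom)) {
    rows <- which(table$chrom == cc)
    pos <- table$pos[rows]
    ok <- !table$is_missing[rows] & !is.na(table$beta[rows])
    good <- which(ok)
    if (length(good) == 0L) next
    # nearest good strictly before each row
    prev_cnt <- cumsum(ok) - ok            # good CpGs strictly before i
    has_prev <- prev_cnt >= 1L
    prev_idx <- good[pmax(prev_cnt, 1L)]
    beta_up[rows[has_prev]] <- table$beta[rows][prev_idx[has_prev]]
    dist_up[rows[has_prev]] <- pos[has_prev] - pos[prev_idx[has_prev]]
    # nearest good strictly after each row
    rev_ok <- rev(ok)
    next_cnt <- rev(cumsum(rev_ok) - rev_ok)  # good CpGs strictly after i
    has_next <- next_cnt >= 1L
    good_rev <- rev(good)
    next_idx <- good_rev[pmax(next_cnt, 1L)]
    beta_down[rows[has_next]] <- table$beta[rows][next_idx[has_next]]
    dist_down[rows[has_next]] <- pos[next_idx[has_next]] - pos[has_next]
  }
  out <- data.frame(beta_up = beta_up, dist_up = dist_up,
                    beta_down = beta_down, dist_down = dist_down)
  out$complete <- !is.na(out$beta_up) & !is.na(out$beta_down)
  if (!is.null(target_index)) out <- out[target_index, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Leave-one-out cross-sample average beta
#'
#' The unweighted mean beta at one CpG over the other samples of the
#' cohort that cover it at `min_depth` or more; undefined (NA) when fewer
#' than `min_others` samples qualify.
#'
#' @param cohort a [cohort_set()].
#' @param chrom,pos CpG coordinate.
#' @param target_sample sample being interrogated (excluded from the mean).
#' @param min_depth coverage a contributing sample must reach (default 10).
#' @param min_others minimum number of qualifying other samples (default 2).
#' @return scalar beta or NA.
#' @export
sample_average <- function(cohort, chrom, pos, target_sample,
                           min_depth = 10L, min_others = 2L) {
  stopifnot(inherits(cohort, "cohort_set"))
  if (!target_sample %in% colnames(cohort$beta))
    stop("unknown target_sample: ", target_sample)
  i <- match(paste(chrom, pos), paste(cohort$index$chrom, cohort$index$pos))
  if (is.na(i)) return(NA_real_)
  others <- setdiff(colnames(cohort$beta), target_sample)
  b <- cohort$beta[i, others]
  d <- cohort$depth[i, others]
  use <- !is.na(b) & d >= min_depth
  if (sum(use) < min_others) return(NA_real_)
  mean(b[use])
}

# vectorized leave-one-out average over the whole union index
sample_average_all <- function(cohort, target_sample, min_depth = 10L,
                               min_others = 2L) {
  others <- setdiff(colnames(cohort$beta), target_sample)
  b <- cohort$beta[, others, drop = FALSE]
  d <- cohort$depth[, others, drop = FALSE]
  use <- !is.na(b) & d >= min_depth
  b[!use] <- 0
  k <- rowSums(use)
  avg <- ifelse(k >= min_others, rowSums(b) / pmax(k, 1L), NA_real_)
  avg
}

#' Feature groups of the ablation taxonomy
#' @return named character vector describing the group letters.
#' @export
feature_groups <- function() {
  c(A = "cross-sample average", N = "nearest non-missing neighbours",
    T = "transcription factor binding sites", R = "recombination rate",
    P = "ATAC peaks", H = "histone marks",
    G = "general genomic annotations", C = "chromatin states")
}

#' Assemble the CpG-by-feature matrix for one target sample
#'
#' Builds one row per CpG of the target sample that passes the exclusion
#' criteria, has a defined cross-sample average (group A requirement
#' applied as a global eligibility rule) and both neighbours present.
#' Feature groups are selected by letter; the default set is
#' `A, N, P, H, G, C`.  Rows with any undefined selected feature are
#' dropped (count recorded in the `n_dropped` attribute).
#'
#' @param cohort a [cohort_set()].
#' @param target_sample sample id within the cohort.
#' @param bundle an [annotation_bundle()] (NULL allowed when no context
#'   groups are selected).
#' @param feature_set character vector of group letters.
#' @param variants,blacklist passed to [apply_exclusion_criteria()].
#' @param autosomes autosome set for the exclusion criteria.
#' @param min_depth,max_depth training depth bounds, see [mark_trainable()].
#' @param min_others sample-average support requirement.
#' @return a `feature_matrix`: data.frame with metadata columns
#'   `chrom, pos, depth, state, target, trainable, imputable` and one
#'   column per selected feature; attributes `feature_names` (ordered) and
#'   `feature_group_of` (named group letters), `target_sample`.
#' @export
assemble_matrix <- function(cohort, target_sample, bundle = NULL,
                            feature_set = c("A", "N", "P", "H", "G", "C"),
                            variants = NULL, blacklist = NULL,
                            autosomes = default_autosomes(),
                            min_depth = 10L, max_depth = 80L,
                            min_others = 2L) {
  stopifnot(inherits(cohort, "cohort_set"))
  unknown <- setdiff(feature_set, names(feature_groups()))
  if (length(unknown) > 0L)
    stop("unknown feature group(s): ", paste(unknown, collapse = ", "))
  if (!target_sample %in% names(cohort$tables))
    stop("unknown target_sample: ", target_sample)
  table <- cohort$tables[[target_sample]]

  flags <- apply_exclusion_criteria(table, variants, blacklist, autosomes)
  savg_all <- sample_average_all(cohort, target_sample,
                                 min_depth = min_depth,
                                 min_others = min_others)
  key <- paste(cohort$index$chrom, cohort$index$pos)
  savg <- savg_all[match(paste(table$chrom, table$pos), key)]
  flags <- mark_trainable(flags, table,
                          sample_average_defined = !is.na(savg),
                          min_depth = min_depth, max_depth = max_depth)
  nb <- neighbor_features(table)

  eligible <- (flags$trainable | flags$imputable) & nb$complete
  idx <- which(eligible)

  feats <- list()
  group_of <- character(0)
  if ("A" %in% feature_set) {
    feats$sample_average <- savg[idx]
    group_of["sample_average"] <- "A"
  }
  if ("N" %in% feature_set) {
    feats$beta_up <- nb$beta_up[idx]
    feats$beta_down <- nb$beta_down[idx]
    feats$dist_up <- nb$dist_up[idx]
    feats$dist_down <- nb$dist_down[idx]
    group_of[c("beta_up", "beta_down", "dist_up", "dist_down")] <- "N"
  }
  state_label <- rep(NA_character_, length(idx))
  ctx_groups <- intersect(feature_set, c("T", "R", "P", "H", "G", "C"))
  if (length(ctx_groups) > 0L) {
    if (is.null(bundle))
      stop("context feature groups selected but no annotation bundle given")
    ctx <- context_features(bundle, table$chrom[idx], table$pos[idx])
    state_label <- attr(ctx, "state")
    cg <- bundle$groups
    for (nm in names(ctx)) {
      g <- if (startsWith(nm, "state_")) "C" else unname(cg[nm])
      if (is.na(g) || !g %in% ctx_groups) next
      feats[[nm]] <- ctx[[nm]]
      group_of[nm] <- g
    }
  } else if (!is.null(bundle) && !is.null(bundle$state_track)) {
    state_label <- state_at(bundle, table$chrom[idx], table$pos[idx])
  }

  meta <- data.frame(chrom = table$chrom[idx], pos = table$pos[idx],
                     depth = table$n_total[idx], state = state_label,
                     target = table$beta[idx],
                     trainable = flags$trainable[idx],
                     imputable = flags$imputable[idx],
                     stringsAsFactors = FALSE)
  fm <- cbind(meta, if (length(feats)) as.data.frame(feats, optional = TRUE))
  feature_names <- names(feats)

  # drop rows with an undefined selected feature (target may be NA only
  # for imputable zero-depth rows, which never enter training)
  if (length(feature_names) > 0L) {
    ok <- stats::complete.cases(fm[, feature_names, drop = FALSE])
  } else ok <- rep(TRUE, nrow(fm))
  n_dropped <- sum(!ok)
  fm <- fm[ok, , drop = FALSE]
  rownames(fm) <- NULL
  structure(fm, class = c("feature_matrix", "data.frame"),
            feature_names = feature_names,
            feature_group_of = group_of[feature_names],
            feature_set = sort(unique(feature_set)),
            target_sample = target_sample,
            n_dropped = n_dropped)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: sample %s, %d CpGs (%d trainable, %d imputable)\n",
              attr(x, "target_sample"), nrow(x), sum(x$trainable),
              sum(x$imputable)))
  cat(sprintf("  %d features [groups %s]: %s\n",
              length(attr(x, "feature_names")),
              paste(attr(x, "feature_set"), collapse = ","),
              paste(utils::head(attr(x, "feature_names"), 8L), collapse = ", ")))
  invisible(x)
}

# subset a feature_matrix by row keeping its attributes
fm_subset <- function(fm, idx) {
  out <- as.data.frame(fm)[idx, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("feature_names", "feature_group_of", "feature_set",
              "target_sample"))
    attr(out, a) <- attr(fm, a)
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Serialize a feature matrix as TSV
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.table(as.data.frame(fm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
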