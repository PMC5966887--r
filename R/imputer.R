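#' Impute low-coverage beta values in one sample
#'
#' Builds features for the imputable CpGs of the target sample (depth
#' below 10, exclusion criteria passed, cross-sample average defined and
#' both neighbours present), predicts with a fitted model and replaces
#' their beta values.  Read counts are never modified; high-coverage
#' records keep their beta bit-for-bit.  Missing CpGs that cannot be
#' imputed keep their observed value and receive a reason code.
#'
#' @param table the sample's [methyl_table()] (must belong to `cohort`).
#' @param cohort the sample's [cohort_set()].
#' @param bundle the [annotation_bundle()] used at training time.
#' @param model a fitted [methboost()] model; its feature registry must
#'   match what `bundle` + `cohort` produce.
#' @param variants,blacklist exclusion inputs, as in [assemble_matrix()].
#' @param autosomes autosome set.
#' @param force re-impute records already flagged imputed.
#' @param quiet suppress the imputation summary message.
#' @return an `imputed_table`: the methylation table with added columns
#'   `imputed_flag`, `original_beta`, `predicted_beta`, `reason_code` and
#'   attribute `source_model`.
#' @export
impute_sample <- function(table, cohort, bundle, model, variants = NULL,
                          blacklist = NULL, autosomes = default_autosomes(),
                          force = FALSE, quiet = TRUE) {
  stopifnot(inherits(table, "methyl_table"), inherits(model, "methboost"))
  sid <- attr(table, "sample_id")
  if (!sid %in% names(cohort$tables))
    stop("sample ", sid, " is not part of the cohort")
  fm <- assemble_matrix(cohort, sid, bundle,
                        feature_set = model$feature_set,
                        variants = variants, blacklist = blacklist,
                        autosomes = autosomes)
  if (!identical(attr(fm, "feature_names"), model$feature_names))
    stop("feature registry mismatch between model and bundle/cohort")
  out <- prepare_imputed(table)
  already <- out$imputed_flag
  target_rows <- which(fm$imputable)
  if (length(target_rows) > 0L) {
    pred <- as.numeric(predict(model, fm_subset(fm, target_rows)))
    key <- paste(out$chrom, out$pos)
    at <- match(paste(fm$chrom[target_rows], fm$pos[target_rows]), key)
    do <- if (force) rep(TRUE, length(at)) else !already[at]
    out$predicted_beta[at[do]] <- pred[do]
    out$beta[at[do]] <- pred[do]
    out$imputed_flag[at[do]] <- TRUE
    out$reason_code[at[do]] <- "imputed"
  }
  out <- annotate_unimputable(out, table, cohort, bundle, variants,
                              blacklist, autosomes)
  if (!quiet) {
    tab <- table(out$reason_code[out$is_missing & !out$imputed_flag])
    message("imputed ", sum(out$imputed_flag), " CpGs; unimputable: ",
            paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  attr(out, "source_model") <- sprintf("%s/%d features/seed %s",
                                       model$backend,
                                       length(model$feature_names),
                                       model$seed)
  out
}

prepare_imputed <- function(table) {
  out <- table
  if (is.null(out$imputed_flag)) out$imputed_flag <- FALSE
  if (is.null(out$original_beta)) out$original_beta <- out$beta
  if (is.null(out$predicted_beta)) out$predicted_beta <- NA_real_
  if (is.null(out$reason_code)) out$reason_code <- NA_character_
  if (!inherits(out, "imputed_table"))
    class(out) <- c("imputed_table", class(table))
  out
}

# reason codes for missing CpGs that were not imputed
annotate_unimputable <- function(out, table, cohort, bundle, variants,
                                 blacklist, autosomes) {
  flags <- apply_exclusion_criteria(table, variants, blacklist, autosomes)
  key <- paste(cohort$index$chrom, cohort$index$pos)
  savg <- sample_average_all(cohort, attr(table, "sample_id"))
  savg <- savg[match(paste(table$chrom, table$pos), key)]
  nb <- neighbor_features(table)
  miss <- which(out$is_missing & !out$imputed_flag)
  reason <- rep(NA_character_, length(miss))
  reason[!flags$autosomal[miss]] <- "non_autosomal"
  reason[is.na(reason) & !flags$variant_clean[miss]] <- "variant"
  reason[is.na(reason) & !flags$blacklist_clean[miss]] <- "blacklist"
  reason[is.na(reason) & is.na(savg[miss])] <- "insufficient_cohort_support"
  reason[is.na(reason) & !nb$complete[miss]] <- "no_neighbor"
  reason[is.na(reason)] <- "ineligible"
  out$reason_code[miss] <- reason
  out
}

#' Impute (and force-replace) beta values at given positions
#'
#' Restricted variant of [impute_sample()] for concordance experiments:
#' predictions are made at exactly the listed positions regardless of
#' sequencing depth, the observed betas being preserved in
#' `original_beta`.  Positions absent from the table are an error.
#'
#' @param table,cohort,bundle,model,variants,blacklist,autosomes as in
#'   [impute_sample()].
#' @param positions data.frame `chrom, pos` of target CpGs (e.g. array
#'   probe coordinates); must all be present in `table`.
#' @return an `imputed_table` (see [impute_sample()]); positions that are
#'   ineligible for feature construction keep their observed beta with a
#'   reason code.
#' @export
impute_at_positions <- function(table, positions, cohort, bundle, model,
                                variants = NULL, blacklist = NULL,
                                autosomes = default_autosomes()) {
  stopifnot(inherits(table, "methyl_table"), inherits(model, "methboost"))
  out <- prepare_imputed(table)
  if (nrow(positions) == 0L) return(out)
  key <- paste(out$chrom, out$pos)
  pkey <- paste(positions$chrom, positions$pos)
  at <- match(pkey, key)
  if (anyNA(at))
    stop("position(s) absent from table: ",
         paste(utils::head(pkey[is.na(at)], 5L), collapse = ", "))
  sid <- attr(table, "sample_id")
  fm <- assemble_matrix(cohort, sid, bundle,
                        feature_set = model$feature_set,
                        variants = variants, blacklist = blacklist,
                        autosomes = autosomes)
  if (!identical(attr(fm, "feature_names"), model$feature_names))
    stop("feature registry mismatch between model and bundle/cohort")
  rows <- match(pkey, paste(fm$chrom, fm$pos))
  ok <- !is.na(rows)
  if (any(ok)) {
    pred <- as.numeric(predict(model, fm_subset(fm, rows[ok])))
    out$predicted_beta[at[ok]] <- pred
    out$beta[at[ok]] <- pred
    out$imputed_flag[at[ok]] <- TRUE
    out$reason_code[at[ok]] <- "imputed"
  }
  out$reason_code[at[!ok]] <- "ineligible"
  attr(out, "source_model") <- sprintf("%s/%d features/seed %s",
                                       model$backend,
                                       length(model$feature_names),
                                       model$seed)
  out
}

#' @export
print.imputed_table <- function(x, ...) {
  cat(sprintf("imputed methyl_table: sample %s, %d CpGs, %d imputed (model %s)\n",
              attr(x, "sample_id"), nrow(x), sum(x$imputed_flag),
              attr(x, "source_model") %||% "?"))
  invisible(x)
}
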