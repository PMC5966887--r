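#' Construct a per-sample CpG methylation table
#'
#' A methylation table holds one sample's CpG records in BED-style 0-based
#' coordinates: `pos` is the position of the forward-strand C of the CpG
#' dyad, `n_meth`/`n_total` are read counts after strand merging, `beta` is
#' `n_meth / n_total` (NA when `n_total == 0`), and `is_missing` flags CpGs
#' sequenced below the depth threshold whose beta estimate is considered
#' unreliable.
#'
#' @param df data.frame with columns `chrom`, `pos`, `n_meth`, `n_total`.
#' @param sample_id sample identifier.
#' @param tissue tissue label shared by a cohort.
#' @param disease_state disease-group label (e.g. `"NGT"`, `"T2D"`).
#' @param min_depth depth below which a CpG is flagged missing (default 10).
#'
#' @return data.frame of class `"methyl_table"` with columns `chrom`, `pos`,
#'   `n_meth`, `n_total`, `beta`, `is_missing`, `nonstandard_contig`, sorted
#'   by (chrom, pos), plus attributes `sample_id`, `tissue`, `disease_state`.
#' @export
methyl_table <- function(df, sample_id, tissue = "unknown",
                         disease_state = "unknown", min_depth = 10L) {
  req <- c("chrom", "pos", "n_meth", "n_total")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(
    chrom = as.character(df$chrom),
    pos = as.integer(df$pos),
    n_meth = as.integer(df$n_meth),
    n_total = as.integer(df$n_total),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$pos) || anyNA(out$n_meth) || anyNA(out$n_total))
    stop("NA in chrom/pos/counts")
  if (any(out$n_meth < 0L) || any(out$n_total < 0L))
    stop("negative read counts")
  bad <- which(out$n_meth > out$n_total)
  if (length(bad) > 0L)
    stop("n_meth > n_total at row(s) ", paste(utils::head(bad, 5L), collapse = ", "))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  dup <- duplicated(paste(out$chrom, out$pos))
  if (any(dup))
    stop("duplicate (chrom, pos): ",
         paste(utils::head(paste(out$chrom, out$pos)[dup], 3L), collapse = "; "))
  rownames(out) <- NULL
  out$beta <- ifelse(out$n_total > 0L, out$n_meth / out$n_total, NA_real_)
  out$is_missing <- out$n_total < as.integer(min_depth)
  out$nonstandard_contig <- !is_standard_contig(out$chrom)
  structure(out,
            class = c("methyl_table", "data.frame"),
            sample_id = as.character(sample_id),
            tissue = as.character(tissue),
            disease_state = as.character(disease_state),
            min_depth = as.integer(min_depth))
}

is_standard_contig <- function(chrom) {
  grepl("^(chr)?([0-9]{1,2}|X|Y|M|MT)$", chrom, ignore.case = TRUE)
}

#' @export
print.methyl_table <- function(x, ...) {
  cat(sprintf("methyl_table: sample %s (%s, %s)\n",
              attr(x, "sample_id"), attr(x, "tissue"), attr(x, "disease_state")))
  cat(sprintf("  %d CpGs on %d contig(s); %.1f%% flagged missing (depth < %d)\n",
              nrow(x), length(unique(x$chrom)),
              100 * mean(x$is_missing), attr(x, "min_depth")))
  invisible(x)
}

# keep the methyl_table class/attributes through a row subset
mt_subset <- function(table, idx) {
  out <- as.data.frame(table)[idx, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("sample_id", "tissue", "disease_state", "min_depth"))
    attr(out, a) <- attr(table, a)
  class(out) <- c("methyl_table", "data.frame")
  out
}

#' Read per-sample CpG methylation calls from a bedGraph file
#'
#' Reads MethylDackel-style bedGraph output (`chrom start end percent nMeth
#' nUnmeth`) or a generic count layout (`chrom start end nMeth nTotal`).
#' The dialect is declared explicitly, never sniffed.  Beta values are
#' always recomputed from counts; when the file's percent column disagrees
#' with the counts by more than 0.5 percentage points a warning is issued
#' and the counts win.  Records on non-standard contigs are retained and
#' flagged (exclusion is filtering policy, not parsing).
#'
#' @param path bedGraph file, optionally gzip-compressed; an optional
#'   leading `track` line is ignored.
#' @param dialect `"methyldackel"` (percent, nMeth, nUnmeth) or `"counts"`
#'   (nMeth, nTotal).
#' @param sample_id,tissue,disease_state labels stored on the table;
#'   `sample_id` defaults to the file name.
#' @param min_depth missingness threshold, see [methyl_table()].
#' @return a [methyl_table()].
#' @export
read_methylation_bedgraph <- function(path,
                                      dialect = c("methyldackel", "counts"),
                                      sample_id = NULL, tissue = "unknown",
                                      disease_state = "unknown",
                                      min_depth = 10L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.(bedGraph|bedgraph|bg|txt|tsv)(\\.gz)?$",
                                           "", basename(path))
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  offset <- 0L
  if (length(lines) > 0L && grepl("^track", lines[1L])) {
    lines <- lines[-1L]
    offset <- 1L
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no data rows in ", path)
  ncol_expected <- if (dialect == "methyldackel") 6L else 5L
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != ncol_expected)
  if (length(bad) > 0L)
    stop(sprintf("malformed row at line %d of %s: expected %d fields, got %d",
                 bad[1L] + offset, path, ncol_expected, nf[bad[1L]]))
  m <- matrix(unlist(fields), ncol = ncol_expected, byrow = TRUE)
  chrom <- m[, 1L]
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop(sprintf("malformed coordinates at line %d of %s", bad + offset, path))
  }
  if (dialect == "methyldackel") {
    pct <- suppressWarnings(as.numeric(m[, 4L]))
    n_meth <- suppressWarnings(as.integer(m[, 5L]))
    n_unmeth <- suppressWarnings(as.integer(m[, 6L]))
    if (anyNA(n_meth) || anyNA(n_unmeth)) {
      bad <- which(is.na(n_meth) | is.na(n_unmeth))[1L]
      stop(sprintf("malformed counts at line %d of %s", bad + offset, path))
    }
    n_total <- n_meth + n_unmeth
    stated <- pct / 100
    recomputed <- ifelse(n_total > 0L, n_meth / n_total, NA_real_)
    off <- !is.na(stated) & !is.na(recomputed) &
      abs(stated - recomputed) > 0.005
    if (any(off))
      warning(sprintf(
        "%d row(s) where the percent column disagrees with counts by > 0.5 points; counts used",
        sum(off)))
  } else {
    n_meth <- suppressWarnings(as.integer(m[, 4L]))
    n_total <- suppressWarnings(as.integer(m[, 5L]))
    if (anyNA(n_meth) || anyNA(n_total)) {
      bad <- which(is.na(n_meth) | is.na(n_total))[1L]
      stop(sprintf("malformed counts at line %d of %s", bad + offset, path))
    }
  }
  methyl_table(data.frame(chrom = chrom, pos = start, n_meth = n_meth,
                          n_total = n_total, stringsAsFactors = FALSE),
               sample_id = sample_id, tissue = tissue,
               disease_state = disease_state, min_depth = min_depth)
}

#' Write a methylation table back to bedGraph
#'
#' Inverse of [read_methylation_bedgraph()]; a read/write cycle reproduces
#' counts losslessly.  The percent column of the MethylDackel dialect is
#' emitted with one decimal (as MethylDackel does); counts carry the data.
#'
#' @param table a [methyl_table()].
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param dialect column layout, as in [read_methylation_bedgraph()].
#' @return `path`, invisibly.
#' @export
write_methylation_bedgraph <- function(table, path,
                                       dialect = c("methyldackel", "counts")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "methyl_table"))
  if (dialect == "methyldackel") {
    pct <- ifelse(table$n_total > 0L,
                  round(100 * table$n_meth / table$n_total, 1), 0)
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", table$chrom, table$pos,
                     table$pos + 1L, format(pct, trim = TRUE),
                     table$n_meth, table$n_total - table$n_meth)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%d\t%d", table$chrom, table$pos,
                     table$pos + 1L, table$n_meth, table$n_total)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a methylation table as annotated TSV
#'
#' Emits `chrom, pos, n_meth, n_total, beta, is_missing, imputed_flag`
#' (the last taken from an imputed table when present, else FALSE).
#'
#' @param table a [methyl_table()] or imputed table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_methylation_tsv <- function(table, path) {
  stopifnot(inherits(table, "methyl_table"))
  out <- data.frame(
    chrom = table$chrom, pos = table$pos, n_meth = table$n_meth,
    n_total = table$n_total, beta = table$beta, is_missing = table$is_missing,
    imputed_flag = if (!is.null(table$imputed_flag)) table$imputed_flag else FALSE,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge the two strands of a CpG dyad
#'
#' Forward- and reverse-strand cytosine calls of one CpG are summed into a
#' single record placed at the forward-strand position, with beta
#' recomputed from the merged counts.
#'
#' @param forward,reverse one-row data.frames (or lists) with `chrom`,
#'   `pos`, `n_meth`, `n_total`; `reverse$pos` must equal `forward$pos + 1`
#'   on the same chromosome.
#' @param min_depth missingness threshold applied to the merged record.
#' @return a one-row data.frame with merged counts, `beta`, `is_missing`.
#' @export
merge_strands <- function(forward, reverse, min_depth = 10L) {
  if (!identical(as.character(forward$chrom), as.character(reverse$chrom)))
    stop("strand records on different chromosomes")
  if (as.integer(reverse$pos) != as.integer(forward$pos) + 1L)
    stop("positions do not form a CpG dyad: ", forward$pos, " / ", reverse$pos)
  n_meth <- as.integer(forward$n_meth) + as.integer(reverse$n_meth)
  n_total <- as.integer(forward$n_total) + as.integer(reverse$n_total)
  if (n_meth > n_total) stop("merged n_meth exceeds n_total")
  data.frame(
    chrom = as.character(forward$chrom), pos = as.integer(forward$pos),
    n_meth = n_meth, n_total = n_total,
    beta = if (n_total > 0L) n_meth / n_total else NA_real_,
    is_missing = n_total < as.integer(min_depth),
    stringsAsFactors = FALSE)
}

#' Flag low-coverage CpGs as missing
#'
#' Sets `is_missing` TRUE exactly where sequencing depth is below
#' `min_depth`; no record is removed.  Idempotent and order-independent.
#'
#' @param table a [methyl_table()].
#' @param min_depth positive integer depth threshold (default 10).
#' @param quiet suppress the missing-fraction message.
#' @return the table with `is_missing` recomputed.
#' @export
flag_missing <- function(table, min_depth = 10L, quiet = TRUE) {
  stopifnot(inherits(table, "methyl_table"))
  min_depth <- as.integer(min_depth)
  if (is.na(min_depth) || min_depth < 1L) stop("min_depth must be >= 1")
  table$is_missing <- table$n_total < min_depth
  attr(table, "min_depth") <- min_depth
  if (!quiet)
    message(sprintf("%.2f%% of %d CpGs below %dx", 100 * mean(table$is_missing),
                    nrow(table), min_depth))
  table
}
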