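#' Read a variant mask from a minimal VCF
#'
#' Parses CHROM/POS/REF/ALT from a plain or gzipped VCF and returns the set
#' of 0-based base positions disturbed by a SNP or a short indel.  Indels
#' longer than 2 bp are ignored.  A variant's disturbed span is
#' `[pos0, pos0 + nchar(REF))`; multi-allelic rows expand per allele.
#'
#' @param path VCF file (header lines starting with `#` are skipped).
#' @param max_indel maximum indel length considered (default 2 bp).
#' @return a `variant_mask`: data.frame with columns `chrom`, `pos`
#'   (0-based, deduplicated).
#' @export
read_variant_mask <- function(path, max_indel = 2L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(variant_mask(character(0), integer(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 5L)) stop("VCF rows need at least CHROM POS ID REF ALT")
  chrom <- vapply(f, `[[`, "", 1L)
  pos1 <- as.integer(vapply(f, `[[`, "", 2L))
  ref <- vapply(f, `[[`, "", 4L)
  alt <- vapply(f, `[[`, "", 5L)
  out_chrom <- character(0)
  out_pos <- integer(0)
  for (i in seq_along(chrom)) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1L]]
    for (a in alts) {
      indel_len <- abs(nchar(ref[i]) - nchar(a))
      if (indel_len > max_indel) next
      span <- seq.int(pos1[i] - 1L, pos1[i] - 1L + nchar(ref[i]) - 1L)
      out_chrom <- c(out_chrom, rep(chrom[i], length(span)))
      out_pos <- c(out_pos, span)
    }
  }
  variant_mask(out_chrom, out_pos)
}

#' Construct a variant mask from positions
#'
#' @param chrom chromosome names.
#' @param pos 0-based disturbed base positions.
#' @return deduplicated `variant_mask` data.frame.
#' @export
variant_mask <- function(chrom, pos) {
  df <- unique(data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("variant_mask", "data.frame")
  df
}

#' Default autosome set
#'
#' chr1-chr22; names are matched with and without the `chr` prefix.
#' @return character vector `"chr1"..."chr22"`.
#' @export
default_autosomes <- function() paste0("chr", 1:22)

normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", chrom, ignore.case = TRUE)
  toupper(x)
}

#' Apply CpG exclusion criteria
#'
#' A CpG fails `variant_clean` if either base of its dyad (`pos` or
#' `pos + 1`) is disturbed by a SNP/short indel; fails `blacklist_clean` if
#' the dyad `[pos, pos+2)` overlaps any blacklist interval; fails
#' `autosomal` if its chromosome is not in the autosome set.
#'
#' @param table a [methyl_table()].
#' @param variants a `variant_mask` (or NULL for none).
#' @param blacklist data.frame of half-open intervals `chrom,start,end`
#'   (or NULL for none).
#' @param autosomes chromosome name set (default chr1-chr22, `chr` prefix
#'   optional).
#' @param quiet suppress the per-reason exclusion counts message.
#' @return an `eligibility_flags` data.frame with logical columns
#'   `autosomal`, `variant_clean`, `blacklist_clean` (one row per CpG) and
#'   an `exclusion_counts` attribute.
#' @export
apply_exclusion_criteria <- function(table, variants = NULL, blacklist = NULL,
                                     autosomes = default_autosomes(),
                                     quiet = TRUE) {
  stopifnot(inherits(table, "methyl_table"))
  if (length(autosomes) == 0L) stop("empty autosome set")
  auto_norm <- unique(normalize_chrom(autosomes))
  autosomal <- normalize_chrom(table$chrom) %in% auto_norm

  variant_clean <- rep(TRUE, nrow(table))
  if (!is.null(variants) && nrow(variants) > 0L) {
    keys <- paste(variants$chrom, variants$pos)
    hit <- paste(table$chrom, table$pos) %in% keys |
      paste(table$chrom, table$pos + 1L) %in% keys
    variant_clean <- !hit
  }

  blacklist_clean <- rep(TRUE, nrow(table))
  if (!is.null(blacklist) && nrow(blacklist) > 0L) {
    blacklist_clean <- !point_overlaps_track(table$chrom, table$pos, blacklist,
                                             width = 2L)
  }

  counts <- c(non_autosomal = sum(!autosomal),
              variant = sum(!variant_clean),
              blacklist = sum(!blacklist_clean))
  if (!quiet)
    message("excluded: ", paste(names(counts), counts, sep = "=", collapse = ", "))
  structure(data.frame(autosomal = autosomal, variant_clean = variant_clean,
                       blacklist_clean = blacklist_clean),
            exclusion_counts = counts,
            class = c("eligibility_flags", "data.frame"))
}

#' Mark CpGs as trainable or imputable
#'
#' Trainable: depth within `[min_depth, max_depth]` (both inclusive), all
#' exclusion criteria passed, and the cross-sample average defined.
#' Imputable: depth below `min_depth`, same other conditions.  The two are
#' mutually exclusive by construction.
#'
#' @param flags output of [apply_exclusion_criteria()].
#' @param table the same [methyl_table()].
#' @param sample_average_defined logical vector, one per CpG, TRUE where at
#'   least two other cohort samples cover the CpG adequately (see
#'   [sample_average()]); defaults to all TRUE for single-table workflows.
#' @param min_depth,max_depth inclusive training depth bounds (10, 80).
#' @return `flags` with added logical columns `trainable` and `imputable`.
#' @export
mark_trainable <- function(flags, table, sample_average_defined = NULL,
                           min_depth = 10L, max_depth = 80L) {
  stopifnot(inherits(flags, "eligibility_flags"), inherits(table, "methyl_table"))
  if (nrow(flags) != nrow(table)) stop("flags/table length mismatch")
  if (min_depth > max_depth) stop("min_depth > max_depth")
  if (is.null(sample_average_defined))
    sample_average_defined <- rep(TRUE, nrow(table))
  clean <- flags$autosomal & flags$variant_clean & flags$blacklist_clean &
    sample_average_defined
  flags$sample_average_defined <- sample_average_defined
  flags$trainable <- clean & table$n_total >= min_depth & table$n_total <= max_depth
  flags$imputable <- clean & table$n_total < min_depth
  flags
}

# 0/1 overlap of width-`width` points against an interval track, via IRanges
point_overlaps_track <- function(chrom, pos, track, width = 2L) {
  out <- rep(FALSE, length(pos))
  if (is.null(track) || nrow(track) == 0L) return(out)
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    tsel <- track$chrom == cc
    if (!any(tsel)) next
    q <- IRanges::IRanges(start = pos[sel] + 1L, width = width)
    s <- IRanges::IRanges(start = track$start[tsel] + 1L,
                          end = track$end[tsel])
    out[sel] <- IRanges::overlapsAny(q, s)
  }
  out
}
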