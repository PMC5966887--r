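#' Read a BED interval track
#'
#' @param path BED / BED-like TSV, half-open 0-based intervals; `track`
#'   header lines are ignored.  A 4th column, when present and requested,
#'   is returned as `label` (character) or `value` (numeric).
#' @param extra `"none"`, `"label"` or `"value"`.
#' @return data.frame `chrom,start,end` (+ `label`/`value`).
#' @export
read_bed_track <- function(path, extra = c("none", "label", "value")) {
  extra <- match.arg(extra)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  need <- if (extra == "none") 3L else 4L
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < need))
    stop("BED rows with fewer than ", need, " fields in ", path)
  df <- data.frame(chrom = vapply(f, `[[`, "", 1L),
                   start = as.integer(vapply(f, `[[`, "", 2L)),
                   end = as.integer(vapply(f, `[[`, "", 3L)),
                   stringsAsFactors = FALSE)
  if (extra == "label") df$label <- vapply(f, `[[`, "", 4L)
  if (extra == "value") df$value <- as.numeric(vapply(f, `[[`, "", 4L))
  if (any(df$end <= df$start)) stop("empty or inverted interval in ", path)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Bundle annotation tracks for feature construction
#'
#' Holds named binary interval tracks (each assigned to a feature group of
#' the ablation taxonomy), one categorical chromatin-state track, and
#' continuous tracks (GC content, recombination rate).  The state track
#' must tile without overlaps so that every CpG maps to at most one state.
#'
#' Feature groups: `A` sample average, `N` neighbours (both built
#' elsewhere), `T` TFBS, `R` recombination rate, `P` ATAC peaks, `H`
#' histone marks, `G` general genomic annotations (GENCODE, CGI and
#' flanks, GC content), `C` chromatin states.
#'
#' @param binary_tracks named list of `chrom,start,end` data.frames.
#' @param state_track data.frame `chrom,start,end,label` or NULL.
#' @param continuous_tracks named list of `chrom,start,end,value`.
#' @param groups named character vector mapping each binary/continuous
#'   track name to its group letter.
#' @param states the full state label set (defaults to the labels present,
#'   sorted); fixes one-hot column order even for states absent locally.
#' @return an `annotation_bundle` list.
#' @export
annotation_bundle <- function(binary_tracks = list(), state_track = NULL,
                              continuous_tracks = list(),
                              groups = NULL, states = NULL) {
  stopifnot(is.list(binary_tracks), is.list(continuous_tracks))
  if (!is.null(state_track)) {
    stopifnot(all(c("chrom", "start", "end", "label") %in% names(state_track)))
    for (cc in unique(state_track$chrom)) {
      s <- state_track[state_track$chrom == cc, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
        stop("overlapping chromatin-state intervals on ", cc)
    }
    if (is.null(states)) states <- sort(unique(state_track$label))
  }
  track_names <- c(names(binary_tracks), names(continuous_tracks))
  if (is.null(groups)) {
    groups <- infer_groups(track_names)
  } else {
    missing_g <- setdiff(track_names, names(groups))
    if (length(missing_g) > 0L)
      stop("tracks without a feature group: ", paste(missing_g, collapse = ", "))
    groups <- groups[track_names]
  }
  structure(list(binary_tracks = binary_tracks, state_track = state_track,
                 continuous_tracks = continuous_tracks, groups = groups,
                 states = states),
            class = "annotation_bundle")
}

# default group assignment by conventional track-name prefixes
infer_groups <- function(track_names) {
  g <- vapply(track_names, function(nm) {
    if (grepl("^atac", nm, ignore.case = TRUE)) "P"
    else if (grepl("^(H[0-9]K|histone)", nm, ignore.case = TRUE)) "H"
    else if (grepl("^tfbs", nm, ignore.case = TRUE)) "T"
    else if (grepl("recomb", nm, ignore.case = TRUE)) "R"
    else "G"
  }, "")
  stats::setNames(g, track_names)
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat("annotation_bundle:\n")
  cat(sprintf("  %d binary track(s): %s\n", length(x$binary_tracks),
              paste(names(x$binary_tracks), collapse = ", ")))
  cat(sprintf("  state track: %s\n",
              if (is.null(x$state_track)) "none"
              else sprintf("%d intervals, %d states", nrow(x$state_track),
                           length(x$states))))
  cat(sprintf("  %d continuous track(s): %s\n", length(x$continuous_tracks),
              paste(names(x$continuous_tracks), collapse = ", ")))
  invisible(x)
}

#' Derive CpG-island shores and shelves
#'
#' Shores are the 2 kb flanks adjacent to each island; shelves the next
#' 2 kb beyond the shores.  Islands take precedence over shores and shores
#' over shelves where the derived regions collide; flanks are truncated at
#' position 0.
#'
#' @param cgi_track data.frame `chrom,start,end` of CpG islands.
#' @param flank flank width in bp (default 2000).
#' @return list with data.frames `shore` and `shelf`.
#' @export
derive_shores_shelves <- function(cgi_track, flank = 2000L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(cgi_track)))
  shore <- list(); shelf <- list()
  for (cc in unique(cgi_track$chrom)) {
    g <- cgi_track[cgi_track$chrom == cc, , drop = FALSE]
    ir_island <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    sh <- c(IRanges::IRanges(pmax(IRanges::start(ir_island) - flank, 1L),
                             pmax(IRanges::start(ir_island) - 1L, 0L)),
            IRanges::IRanges(IRanges::end(ir_island) + 1L,
                             IRanges::end(ir_island) + flank))
    sh <- sh[IRanges::width(sh) > 0L]
    ir_shore <- IRanges::setdiff(IRanges::reduce(sh), ir_island)
    sl <- c(IRanges::IRanges(pmax(IRanges::start(ir_island) - 2L * flank, 1L),
                             pmax(IRanges::start(ir_island) - flank - 1L, 0L)),
            IRanges::IRanges(IRanges::end(ir_island) + flank + 1L,
                             IRanges::end(ir_island) + 2L * flank))
    sl <- sl[IRanges::width(sl) > 0L]
    ir_shelf <- IRanges::setdiff(IRanges::setdiff(IRanges::reduce(sl), ir_island),
                                 ir_shore)
    if (length(ir_shore) > 0L)
      shore[[cc]] <- data.frame(chrom = cc,
                                start = IRanges::start(ir_shore) - 1L,
                                end = IRanges::end(ir_shore),
                                stringsAsFactors = FALSE)
    if (length(ir_shelf) > 0L)
      shelf[[cc]] <- data.frame(chrom = cc,
                                start = IRanges::start(ir_shelf) - 1L,
                                end = IRanges::end(ir_shelf),
                                stringsAsFactors = FALSE)
  }
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  list(shore = if (length(shore)) do.call(rbind, unname(shore)) else empty,
       shelf = if (length(shelf)) do.call(rbind, unname(shelf)) else empty)
}

#' Merge TFBS motif tracks by factor and intersect with open chromatin
#'
#' Hits from multiple motifs of the same transcription factor are merged,
#' and only hits overlapping an ATAC peak are retained, both done once at
#' bundle-load time.
#'
#' @param tfbs_tracks named list of `chrom,start,end` data.frames; names of
#'   the form `FACTOR` or `FACTOR_motifN` are merged by the factor part.
#' @param atac ATAC-peak track used as the open-chromatin filter (NULL to
#'   skip filtering).
#' @return named list of merged, filtered tracks (one per factor),
#'   names prefixed `tfbs_`.
#' @export
merge_tfbs_tracks <- function(tfbs_tracks, atac = NULL) {
  factor_of <- sub("_motif[0-9]+$", "", names(tfbs_tracks))
  out <- list()
  for (fac in unique(factor_of)) {
    df <- do.call(rbind, tfbs_tracks[factor_of == fac])
    merged <- list()
    for (cc in unique(df$chrom)) {
      d <- df[df$chrom == cc, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      if (!is.null(atac)) {
        a <- atac[atac$chrom == cc, , drop = FALSE]
        keep <- if (nrow(a) > 0L)
          IRanges::overlapsAny(ir, IRanges::IRanges(a$start + 1L, a$end))
        else rep(FALSE, length(ir))
        ir <- ir[keep]
      }
      if (length(ir) > 0L)
        merged[[cc]] <- data.frame(chrom = cc, start = IRanges::start(ir) - 1L,
                                   end = IRanges::end(ir),
                                   stringsAsFactors = FALSE)
    }
    out[[paste0("tfbs_", fac)]] <- if (length(merged))
      do.call(rbind, unname(merged))
    else data.frame(chrom = character(0), start = integer(0), end = integer(0))
  }
  out
}

#' Genomic-context features at CpG positions
#'
#' One 0/1 column per binary track (1 iff the dyad `[pos, pos+2)` overlaps
#' at least one interval), one one-hot indicator per chromatin state, and
#' continuous values looked up by containing interval (NA where no
#' interval covers the CpG).
#'
#' @param bundle an [annotation_bundle()].
#' @param chrom,pos CpG coordinates (vectors of equal length).
#' @return data.frame of context features, one row per CpG; attribute
#'   `state` carries the raw state label per CpG.
#' @export
context_features <- function(bundle, chrom, pos) {
  stopifnot(inherits(bundle, "annotation_bundle"), length(chrom) == length(pos))
  n <- length(pos)
  out <- list()
  for (nm in names(bundle$binary_tracks))
    out[[nm]] <- as.numeric(point_overlaps_track(chrom, pos,
                                                 bundle$binary_tracks[[nm]],
                                                 width = 2L))
  state <- rep(NA_character_, n)
  if (!is.null(bundle$state_track)) {
    state <- state_at(bundle, chrom, pos)
    for (s in bundle$states)
      out[[paste0("state_", gsub("[^A-Za-z0-9]+", "_", s))]] <-
        as.numeric(!is.na(state) & state == s)
  }
  for (nm in names(bundle$continuous_tracks))
    out[[nm]] <- continuous_at(bundle$continuous_tracks[[nm]], chrom, pos)
  df <- if (length(out)) as.data.frame(out, optional = TRUE)
  else data.frame(row.names = seq_len(n))
  attr(df, "state") <- state
  df
}

#' Chromatin state label at CpG positions
#'
#' @param bundle an [annotation_bundle()] with a state track.
#' @param chrom,pos CpG coordinates.
#' @return character vector of labels (NA where unannotated).
#' @export
state_at <- function(bundle, chrom, pos) {
  st <- bundle$state_track
  if (is.null(st)) return(rep(NA_character_, length(pos)))
  out <- rep(NA_character_, length(pos))
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    s <- st[st$chrom == cc, , drop = FALSE]
    if (nrow(s) == 0L) next
    s <- s[order(s$start), , drop = FALSE]
    # non-overlapping sorted intervals: findInterval on starts
    idx <- findInterval(pos[sel], s$start)
    ok <- idx >= 1L & pos[sel] < s$end[pmax(idx, 1L)]
    out[sel][ok] <- s$label[idx[ok]]
  }
  out
}

continuous_at <- function(track, chrom, pos) {
  out <- rep(NA_real_, length(pos))
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    s <- track[track$chrom == cc, , drop = FALSE]
    if (nrow(s) == 0L) next
    s <- s[order(s$start), , drop = FALSE]
    idx <- findInterval(pos[sel], s$start)
    ok <- idx >= 1L & pos[sel] < s$end[pmax(idx, 1L)]
    out[sel][ok] <- s$value[idx[ok]]
  }
  out
}

#' Write an interval track as BED
#'
#' @param track data.frame `chrom,start,end` plus optional `label`/`value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(track, path) {
  cols <- intersect(c("chrom", "start", "end", "label", "value"), names(track))
  utils::write.table(track[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
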