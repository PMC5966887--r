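#' Simulation configuration for synthetic WGBS cohorts
#'
#' Defaults describe a realistic deep-coverage human WGBS study: ~50 bp
#' mean inter-CpG spacing, ~30x mean coverage with an overdispersed
#' (negative binomial) depth distribution producing a substantial
#' depth<10 tail, bimodal state-dependent beta values, strong cross-sample
#' concordance within a tissue (`kappa`), and a minority of planted
#' high-variance blocks enriched for intermediate methylation.
#'
#' @param seed master seed; every stage derives its own substream from it.
#' @param n_samples samples per cohort (default 12).
#' @param cohorts named integer vector of cohort sizes for multi-tissue
#'   studies (NULL = one cohort of `n_samples`); names are
#'   `tissue.disease` labels, e.g. `c(adipose_NGT = 12, islet_NGT = 10)`.
#' @param chrom_length simulated chromosome length in bp (default 1e6).
#' @param mean_spacing mean inter-CpG spacing in bp (default 50).
#' @param kappa cross-sample concordance in `[0, 1]`: a sample's true beta
#'   is `kappa * tissue_latent + (1 - kappa) * independent_draw`.
#' @param decay_length bp scale of the distance-decaying correlation of
#'   the latent methylation profile (default 300).
#' @param block_fraction fraction of CpGs inside planted high-variance
#'   blocks (default 0.24; "high variance" is operationally the top
#'   quartile of across-sample variances, so the planted mass sits just
#'   under one quarter).
#' @param block_kappa concordance inside blocks (default 0.5, low).
#' @param block_mean_cpgs mean CpGs per planted block (default 8).
#' @param coverage_mean,coverage_dispersion negative binomial depth model
#'   (mu 30, size 2: ~15% of CpGs fall below 10x).
#' @param coverage_profile_sd log-scale sd of a smooth coverage-efficiency
#'   profile shared by all samples (mappability/GC-bias surrogate; 0
#'   disables it).  Creates the regional missingness clusters seen in
#'   real WGBS, where low-coverage stretches co-occur across samples.
#' @param coverage_profile_length bp decay scale of that profile.
#' @param array_noise_sd Gaussian noise sd of simulated array betas.
#' @param array_probe_fraction fraction of CpGs carrying an array probe.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_samples = 12L, cohorts = NULL,
                       chrom_length = 1e6, mean_spacing = 50,
                       kappa = 0.9, decay_length = 300,
                       block_fraction = 0.24, block_kappa = 0.5,
                       block_mean_cpgs = 8, coverage_mean = 30,
                       coverage_dispersion = 2,
                       coverage_profile_sd = 0.5,
                       coverage_profile_length = 2000,
                       array_noise_sd = 0.03,
                       array_probe_fraction = 0.03) {
  if (is.null(cohorts)) cohorts <- c(tissueA_NGT = as.integer(n_samples))
  cfg <- list(seed = as.integer(seed), cohorts = cohorts,
              chrom_length = chrom_length, mean_spacing = mean_spacing,
              kappa = kappa, decay_length = decay_length,
              block_fraction = block_fraction, block_kappa = block_kappa,
              block_mean_cpgs = block_mean_cpgs,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              coverage_profile_sd = coverage_profile_sd,
              coverage_profile_length = coverage_profile_length,
              array_noise_sd = array_noise_sd,
              array_probe_fraction = array_probe_fraction,
              states = default_state_model())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$mean_spacing > 0, cfg$chrom_length > 1000,
            cfg$kappa >= 0, cfg$kappa <= 1,
            cfg$block_kappa >= 0, cfg$block_kappa <= 1,
            cfg$block_fraction >= 0, cfg$block_fraction < 1,
              cfg$coverage_mean > 0, cfg$coverage_dispersion > 0,
            cfg$coverage_profile_sd >= 0, cfg$coverage_profile_length > 0,
            cfg$array_noise_sd >= 0,
            cfg$array_probe_fraction > 0, cfg$array_probe_fraction <= 1,
            all(cfg$cohorts >= 3L))
  if (abs(sum(cfg$states$freq) - 1) > 1e-8)
    stop("state frequencies must sum to 1")
  invisible(cfg)
}

# 13-state segmentation model: frequency, mean segment length (bp) and the
# low/mid/high beta-mixture weights of each state.  TSS states are lowly
# methylated, transcribed/quiescent states highly, enhancers dispersed.
default_state_model <- function() {
  data.frame(
    state = c("TSS_Active", "TSS_Flanking", "TSS_Bivalent",
              "Enhancer_Active", "Enhancer_Weak", "Enhancer_Genic",
              "Transcription_Strong", "Transcription_Weak",
              "Repressed_Polycomb", "Repressed_Weak", "ZNF_Repeats",
              "Heterochromatin", "Quiescent"),
    freq = c(0.02, 0.03, 0.01, 0.03, 0.04, 0.02, 0.10, 0.20,
             0.02, 0.03, 0.01, 0.09, 0.40),
    seglen = c(600, 800, 600, 700, 700, 700, 3000, 2500,
               1500, 1500, 1000, 4000, 5000),
    w_low = c(0.90, 0.60, 0.70, 0.20, 0.15, 0.10, 0.03, 0.05,
              0.30, 0.20, 0.05, 0.05, 0.03),
    w_mid = c(0.08, 0.30, 0.20, 0.50, 0.45, 0.40, 0.07, 0.10,
              0.40, 0.35, 0.15, 0.15, 0.09),
    stringsAsFactors = FALSE)
}

# beta-mixture components shared by all states
MIX_SHAPES <- list(low = c(0.5, 15), mid = c(4, 4), high = c(15, 0.5))

# inverse-CDF of the state's low/mid/high mixture via slice coupling:
# u < w_low -> low component, u < w_low + w_mid -> mid, else high.  The
# marginal is exactly the mixture; the map keeps low u -> low beta.
qmix_state <- function(u, w_low, w_mid) {
  w_high <- 1 - w_low - w_mid
  out <- numeric(length(u))
  a1 <- w_low; a2 <- w_low + w_mid
  i1 <- u < a1; i2 <- !i1 & u < a2; i3 <- !i1 & !i2
  if (any(i1)) out[i1] <- stats::qbeta(u[i1] / w_low[i1],
                                       MIX_SHAPES$low[1], MIX_SHAPES$low[2])
  if (any(i2)) out[i2] <- stats::qbeta((u[i2] - a1[i2]) / w_mid[i2],
                                       MIX_SHAPES$mid[1], MIX_SHAPES$mid[2])
  if (any(i3)) out[i3] <- stats::qbeta((u[i3] - a2[i3]) / w_high[i3],
                                       MIX_SHAPES$high[1], MIX_SHAPES$high[2])
  out
}

# expected mixture mass outside (lo, hi) implied by a config (used by
# distributional tests): weighted over states by freq
mixture_extreme_mass <- function(cfg, lo = 0.2, hi = 0.8) {
  s <- cfg$states
  w_high <- 1 - s$w_low - s$w_mid
  mass_c <- function(shapes) stats::pbeta(lo, shapes[1], shapes[2]) +
    1 - stats::pbeta(hi, shapes[1], shapes[2])
  per_state <- s$w_low * mass_c(MIX_SHAPES$low) +
    s$w_mid * mass_c(MIX_SHAPES$mid) + w_high * mass_c(MIX_SHAPES$high)
  sum(s$freq * per_state)
}

#' Simulate a multi-cohort WGBS study with known ground truth
#'
#' One synthetic chromosome shared by all cohorts: CpG positions with
#' geometric inter-arrivals, a renewal-process chromatin-state
#' segmentation, a latent tissue methylation profile with
#' distance-decaying correlation (Gaussian copula over the state's beta
#' mixture), planted low-concordance intermediate-methylation blocks,
#' negative-binomial sequencing depth and binomial methylated-read counts.
#' Binary context tracks (ATAC, histone marks, CGI with derived
#' shores/shelves, exon annotations) are placed correlated with the
#' low-methylation states; GC content and recombination rate tile the
#' chromosome.
#'
#' @param config a [sim_config()].
#' @return list with `cohorts` (named list of [cohort_set()]), `bundle`
#'   (an [annotation_bundle()]), and `truth` (list: `index` chrom/pos,
#'   `state` per CpG, `true_beta` named list of CpG-by-sample matrices,
#'   `blocks` planted block coordinates with CpG index ranges, `config`).
#' @export
simulate_study <- function(config) {
  validate_sim_config(config)
  cfg <- config
  chrom <- "chr1"

  # --- CpG positions (substream 1)
  set.seed(cfg$seed + 1L)
  n_guess <- ceiling(cfg$chrom_length / cfg$mean_spacing * 1.3)
  gaps <- stats::rgeom(n_guess, 1 / cfg$mean_spacing) + 1L
  pos <- 100L + cumsum(gaps)
  pos <- pos[pos < cfg$chrom_length - 2L]
  n <- length(pos)

  # --- chromatin-state segmentation (substream 2)
  set.seed(cfg$seed + 2L)
  segs <- list(); total <- 0; k <- 0L
  while (total < cfg$chrom_length) {
    k <- k + 1L
    si <- sample.int(nrow(cfg$states), 1L, prob = cfg$states$freq)
    len <- max(200, round(stats::rexp(1L, 1 / cfg$states$seglen[si])))
    segs[[k]] <- data.frame(chrom = chrom, start = total,
                            end = min(total + len, cfg$chrom_length),
                            label = cfg$states$state[si],
                            stringsAsFactors = FALSE)
    total <- total + len
  }
  state_track <- do.call(rbind, segs)
  seg_idx <- findInterval(pos, state_track$start)
  cpg_state <- state_track$label[seg_idx]
  srow <- match(cpg_state, cfg$states$state)

  # --- planted high-variance blocks (substream 3), as CpG-index runs
  set.seed(cfg$seed + 3L)
  blocks <- plant_blocks(n, cfg$block_fraction, cfg$block_mean_cpgs)
  in_block <- rep(FALSE, n)
  for (b in seq_len(nrow(blocks)))
    in_block[blocks$first_idx[b]:blocks$last_idx[b]] <- TRUE
  blocks$chrom <- rep(chrom, nrow(blocks))
  blocks$start <- pos[blocks$first_idx]
  blocks$end <- pos[blocks$last_idx] + 2L

  # --- latent profile with distance-decaying correlation (substream 4)
  set.seed(cfg$seed + 4L)
  rho <- exp(-diff(pos) / cfg$decay_length)
  u <- stats::pnorm(ar_gaussian(n, rho))

  # --- shared coverage-efficiency profile (substream 6): smooth
  #     log-normal multiplier on the mean depth, common to all samples,
  #     producing regional low-coverage (missingness) clusters
  set.seed(cfg$seed + 6L)
  cov_factor <- rep(1, n)
  if (cfg$coverage_profile_sd > 0) {
    rho_cov <- exp(-diff(pos) / cfg$coverage_profile_length)
    cov_factor <- exp(cfg$coverage_profile_sd * ar_gaussian(n, rho_cov) -
                        cfg$coverage_profile_sd^2 / 2)
  }
  latent <- qmix_state(u, cfg$states$w_low[srow], cfg$states$w_mid[srow])

  cohort_names <- names(cfg$cohorts)
  true_beta <- list()
  cohorts <- list()
  for (ci in seq_along(cfg$cohorts)) {
    n_s <- cfg$cohorts[[ci]]
    cname <- cohort_names[ci]
    tissue <- sub("_[^_]*$", "", cname)
    disease <- sub("^.*_", "", cname)

    # --- cohort-level latent: shared outside blocks, cohort-specific
    #     intermediate-centred inside blocks (substream 10+ci)
    set.seed(cfg$seed + 10L + ci)
    cohort_latent <- latent
    for (b in seq_len(nrow(blocks))) {
      i <- blocks$first_idx[b]:blocks$last_idx[b]
      centre <- stats::rbeta(1L, 2, 2)
      cohort_latent[i] <- pmin(pmax(centre + stats::rnorm(length(i), 0, 0.15),
                                    0.02), 0.98)
    }

    # --- per-sample true betas, depths and counts (substream 100+ci)
    set.seed(cfg$seed + 100L + ci)
    beta_mat <- matrix(NA_real_, n, n_s)
    tables <- vector("list", n_s)
    for (s in seq_len(n_s)) {
      # sample-specific deviations are regionally correlated (DMR-like),
      # with the same distance decay as the tissue profile
      u_e <- stats::pnorm(ar_gaussian(n, rho))
      e <- qmix_state(u_e, cfg$states$w_low[srow], cfg$states$w_mid[srow])
      e[in_block] <- stats::qbeta(u_e[in_block], 2, 2)
      kap <- ifelse(in_block, cfg$block_kappa, cfg$kappa)
      x <- kap * cohort_latent + (1 - kap) * e
      beta_mat[, s] <- x
      depth <- stats::rnbinom(n, mu = cfg$coverage_mean * cov_factor,
                              size = cfg$coverage_dispersion)
      n_meth <- stats::rbinom(n, depth, x)
      tables[[s]] <- methyl_table(
        data.frame(chrom = chrom, pos = pos, n_meth = n_meth,
                   n_total = depth, stringsAsFactors = FALSE),
        sample_id = sprintf("%s_s%02d", cname, s),
        tissue = tissue, disease_state = disease)
    }
    colnames(beta_mat) <- vapply(tables, attr, "", "sample_id")
    true_beta[[cname]] <- beta_mat
    cohorts[[cname]] <- cohort_set(tables)
  }

  # --- annotation tracks correlated with low-beta states (substream 5)
  set.seed(cfg$seed + 5L)
  bundle <- simulate_tracks(state_track, cfg)

  list(cohorts = cohorts, bundle = bundle,
       truth = list(index = data.frame(chrom = chrom, pos = pos,
                                       stringsAsFactors = FALSE),
                    state = cpg_state, in_block = in_block,
                    true_beta = true_beta, blocks = blocks,
                    config = cfg))
}

#' Simulate a single cohort
#'
#' Convenience wrapper around [simulate_study()] for one tissue/disease
#' group.
#'
#' @param config a [sim_config()].
#' @return list `cohort`, `bundle`, `truth` (see [simulate_study()]).
#' @export
simulate_cohort <- function(config) {
  if (length(config$cohorts) != 1L)
    stop("simulate_cohort expects a single-cohort config; use simulate_study")
  out <- simulate_study(config)
  list(cohort = out$cohorts[[1L]], bundle = out$bundle, truth = out$truth)
}

# stationary Gaussian AR(1) with per-step correlations rho
ar_gaussian <- function(n, rho) {
  z <- numeric(n)
  z[1L] <- stats::rnorm(1L)
  eps <- stats::rnorm(n - 1L)
  for (i in 2:n) z[i] <- rho[i - 1L] * z[i - 1L] +
    sqrt(1 - rho[i - 1L]^2) * eps[i - 1L]
  z
}

# non-overlapping CpG-index runs covering ~ frac of CpGs, mean length
# mean_cpgs (>= 2), uniformly placed
plant_blocks <- function(n, frac, mean_cpgs) {
  if (frac <= 0)
    return(data.frame(first_idx = integer(0), last_idx = integer(0)))
  n_blocks <- max(1L, round(frac * n / mean_cpgs))
  lens <- 2L + stats::rpois(n_blocks, mean_cpgs - 2)
  starts <- sort(sample.int(n, n_blocks))
  first <- integer(0); last <- integer(0)
  prev_end <- -1L
  for (i in seq_len(n_blocks)) {
    a <- starts[i]
    if (a <= prev_end + 1L) next       # keep blocks separated by >= 1 CpG
    b <- min(a + lens[i] - 1L, n)
    first <- c(first, a); last <- c(last, b)
    prev_end <- b
  }
  data.frame(first_idx = first, last_idx = last)
}

# context tracks: ATAC/H3K4me3/CGI over TSS-like segments, H3K27ac over
# enhancers, exons over transcribed states; GC and recombination tiles
simulate_tracks <- function(state_track, cfg) {
  place <- function(labels, p, width) {
    s <- state_track[state_track$label %in% labels, , drop = FALSE]
    keep <- stats::runif(nrow(s)) < p
    s <- s[keep, , drop = FALSE]
    if (nrow(s) == 0L)
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
    w <- pmin(width, s$end - s$start)
    mid <- (s$start + s$end) %/% 2L
    data.frame(chrom = s$chrom, start = as.integer(mid - w %/% 2L),
               end = as.integer(mid - w %/% 2L + w), stringsAsFactors = FALSE)
  }
  tss <- c("TSS_Active", "TSS_Flanking", "TSS_Bivalent")
  enh <- c("Enhancer_Active", "Enhancer_Weak", "Enhancer_Genic")
  atac <- place(c(tss, enh), 0.7, 400L)
  h3k4me3 <- place(tss, 0.8, 1000L)
  h3k27ac <- place(c(enh, "TSS_Flanking"), 0.6, 800L)
  cgi <- place(tss, 0.5, 600L)
  exon <- place(c("Transcription_Strong", "Transcription_Weak"), 0.5, 500L)
  ss <- derive_shores_shelves(cgi)

  chrom <- state_track$chrom[1L]
  len <- max(state_track$end)
  tile_starts <- seq(0L, len - 1L, by = 1000L)
  gc <- data.frame(chrom = chrom, start = tile_starts,
                   end = pmin(tile_starts + 1000L, len))
  near_cgi <- point_overlaps_track(gc$chrom, gc$start, cgi, width = 1000L)
  gc$value <- pmin(pmax(stats::rnorm(nrow(gc), 0.42, 0.05) +
                          0.15 * near_cgi, 0.2), 0.85)
  rec <- data.frame(chrom = chrom, start = tile_starts,
                    end = pmin(tile_starts + 1000L, len),
                    value = stats::rexp(length(tile_starts), 1))

  annotation_bundle(
    binary_tracks = list(atac_peak = atac, H3K4me3 = h3k4me3,
                         H3K27ac = h3k27ac, cgi = cgi,
                         cgi_shore = ss$shore, cgi_shelf = ss$shelf,
                         gencode_exon = exon),
    state_track = state_track,
    continuous_tracks = list(gc_content = gc, recomb_rate = rec),
    groups = c(atac_peak = "P", H3K4me3 = "H", H3K27ac = "H", cgi = "G",
               cgi_shore = "G", cgi_shelf = "G", gencode_exon = "G",
               gc_content = "G", recomb_rate = "R"))
}

#' Simulate array-style reference betas from ground truth
#'
#' A random CpG subset (Bernoulli `probe_fraction` per CpG) receives a
#' depth-independent beta estimate: the sample's true beta plus Gaussian
#' noise, clipped to `[0, 1]`.
#'
#' @param truth the `truth` element of [simulate_study()].
#' @param sample_id sample whose true betas are probed; must exist in one
#'   of the truth's cohorts.
#' @param noise_sd Gaussian noise sd (>= 0; default from the config).
#' @param probe_fraction probe density (default from the config).
#' @param seed sampling seed (default derived from the config seed).
#' @return data.frame `probe_id, chrom, pos, beta, probe_type`.
#' @export
simulate_array <- function(truth, sample_id, noise_sd = NULL,
                           probe_fraction = NULL, seed = NULL) {
  cfg <- truth$config
  if (is.null(noise_sd)) noise_sd <- cfg$array_noise_sd
  if (is.null(probe_fraction)) probe_fraction <- cfg$array_probe_fraction
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (probe_fraction <= 0 || probe_fraction > 1)
    stop("probe_fraction must be in (0, 1]")
  if (is.null(seed)) seed <- cfg$seed + 7L
  col <- NULL
  for (cb in truth$true_beta)
    if (sample_id %in% colnames(cb)) { col <- cb[, sample_id]; break }
  if (is.null(col)) stop("unknown sample_id: ", sample_id)
  set.seed(seed)
  on_array <- stats::runif(nrow(truth$index)) < probe_fraction
  idx <- which(on_array)
  beta <- pmin(pmax(col[idx] + stats::rnorm(length(idx), 0, noise_sd), 0), 1)
  data.frame(probe_id = sprintf("cg%08d", idx),
             chrom = truth$index$chrom[idx], pos = truth$index$pos[idx],
             beta = beta,
             probe_type = sample(c("I", "II"), length(idx), replace = TRUE,
                                 prob = c(0.16, 0.84)),
             stringsAsFactors = FALSE)
}

#' Write a simulated study to disk in standard formats
#'
#' Emits one bedGraph per sample, the annotation BED tracks, the
#' chromatin-state BED, continuous tracks as 4-column BED, and a truth
#' TSV per cohort.
#'
#' @param study output of [simulate_study()].
#' @param outdir output directory (created).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (cname in names(study$cohorts))
    for (t in study$cohorts[[cname]]$tables)
      write_methylation_bedgraph(
        t, file.path(outdir, paste0(attr(t, "sample_id"), ".bedGraph")))
  b <- study$bundle
  for (nm in names(b$binary_tracks))
    write_bed_track(b$binary_tracks[[nm]], file.path(outdir, paste0(nm, ".bed")))
  write_bed_track(b$state_track, file.path(outdir, "chromatin_states.bed"))
  for (nm in names(b$continuous_tracks))
    write_bed_track(b$continuous_tracks[[nm]], file.path(outdir, paste0(nm, ".bed")))
  for (cname in names(study$truth$true_beta)) {
    tb <- study$truth$true_beta[[cname]]
    df <- cbind(study$truth$index, state = study$truth$state,
                in_block = study$truth$in_block, as.data.frame(tb))
    utils::write.table(df, file.path(outdir, paste0("truth_", cname, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(study$truth$blocks,
                     file.path(outdir, "planted_blocks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
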