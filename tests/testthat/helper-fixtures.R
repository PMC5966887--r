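# shared fixtures, built in code and memoized per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small single-cohort study: 4 samples, 200 kb (~4k CpGs)
sim_small <- function() cached("sim_small", {
  simulate_cohort(sim_config(seed = 42, n_samples = 4, chrom_length = 2e5))
})

# mid-size single-cohort study used by model-level tests
sim_mid <- function() cached("sim_mid", {
  simulate_cohort(sim_config(seed = 7, n_samples = 5, chrom_length = 4e5))
})

fm_mid <- function() cached("fm_mid", {
  sim <- sim_mid()
  assemble_matrix(sim$cohort, names(sim$cohort$tables)[1], sim$bundle)
})

model_mid <- function() cached("model_mid", {
  methboost(fm_mid(), seed = 11)
})

# hand-built methylation table
toy_table <- function(pos, n_meth, n_total, chrom = "chr1",
                      sample_id = "s1", ...) {
  methyl_table(data.frame(chrom = chrom, pos = pos, n_meth = n_meth,
                          n_total = n_total, stringsAsFactors = FALSE),
               sample_id = sample_id, ...)
}

# cohort of >= 3 toy tables at shared positions, betas given as a matrix
# (CpG x sample) realized exactly with depth `depth`
toy_cohort <- function(pos, beta_mat, depth = 20L, tissue = "muscle",
                       disease_state = "NGT", chrom = "chr1") {
  depth_mat <- if (is.matrix(depth)) depth
  else matrix(depth, nrow(beta_mat), ncol(beta_mat))
  tables <- lapply(seq_len(ncol(beta_mat)), function(s) {
    n_total <- depth_mat[, s]
    n_meth <- round(beta_mat[, s] * n_total)
    methyl_table(data.frame(chrom = chrom, pos = pos, n_meth = n_meth,
                            n_total = n_total, stringsAsFactors = FALSE),
                 sample_id = paste0("s", s), tissue = tissue,
                 disease_state = disease_state)
  })
  cohort_set(tables)
}
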