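# Shared fixtures: the benchmark kinetic parameterization and small
# generated series. Everything is built in code at test time.

benchmark_model <- function(n) hill_model(n, v_max = 0.0102, K_m = 0.30)

# noiseless series from the benchmark design (fast: coarse grids are fine
# because the closed-form solution family does the prediction work)
noiseless_series <- function(n, m_points = 15L) {
  generate_series(default_design(n, noise = noise_model(0),
                                 m_points = m_points, n_replicates = 1L), 0L)
}

noisy_design <- function(n, seed = 1L, ...) {
  default_design(n, master_seed = seed, ...)
}

# quick fit options for tests that do not probe optimizer robustness
fast_options <- function() fit_options(multistart = 2L, seed = 1L)

# scratch paths under the session tempdir (cleaned up with the session)
withr_local_file <- function(name) tempfile(fileext = paste0("-", name))
withr_local_dir <- function(name) {
  d <- tempfile(paste0(name, "-"))
  dir.create(d, recursive = TRUE)
  d
}
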