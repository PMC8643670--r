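# Shared fixture builders.  Everything is generated in code, seeded.

quiet_params <- function(...) {
  population_params(noise_sigma_log = 0, dna_noise_sigma_log = 0, ...)
}

quiet_render <- function(...) {
  render_params(read_noise_sigma = 0, background_level = 0, ...)
}

# a small rendered growth scene and its analysis, reused across files
small_experiment <- function(n = 300, seed = 42, ...) {
  run_simulated_experiment(population_params(n_cells = n, seed = seed),
                           render_params(seed = seed + 1), ...)
}

# records drawn uniformly over the gating space, for brute-force checks
random_records <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    cell_id = seq_len(n),
    hoechst_norm = stats::runif(n, 0.8, 2.2),
    edu = stats::runif(n, -10, 3),
    mcm2 = stats::runif(n, -3, 2),
    mcm3 = stats::runif(n, -3, 2),
    cdt1 = stats::runif(n, -3, 2.5),
    h4k20me1 = stats::runif(n, -5, 2),
    h4k20me2 = stats::runif(n, -5, 2)
  )
}
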