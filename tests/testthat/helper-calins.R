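# small noiseless configurations used across tests

quiet_population <- function(n_exc = 1, n_inh = 0, ...) {
  sample_population(n_exc, n_inh, responsive_fraction = 1, seed = 1,
    spontaneous_rate = 0, noise_sigma = 0, ...)
}

tiny_config <- function(...) {
  sim_config(n_excitatory = 3, trials_per_intensity = 2,
    intensities = c(0, 0.42, 0.76), spontaneous_rate = 0,
    noise_sigma = 0.02, ...)
}

# noiseless trial-averaged table for a small cohort
noiseless_avg <- function(n = 4, intensities = c(0, 0.42, 0.76)) {
  cfg <- sim_config(n_excitatory = n, trials_per_intensity = 1,
    intensities = intensities, spontaneous_rate = 0, noise_sigma = 0)
  ds <- simulate_dataset(cfg, seed = 11)
  list(ds = ds, avg = average_responses(ds))
}

single_layer <- function(mu_a = 3, mu_s = 0, g = 0, n = 1.33) {
  tibble::tibble(name = "medium", thickness_mm = NA,
    mu_a = mu_a, mu_s = mu_s, g = g, n = n)
}
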