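# Shared small-scale configurations for the test suite. Problem sizes are
# kept modest; the acceptance tests use the full reported-run settings.

quick_cfg <- function(n_photons = 2e4, seed = 1, ...) {
  tally_config(n_photons = n_photons, seed = seed, ...)
}

quick_fit_cfg <- function(seed = 1, ...) {
  fit_config(n_particles = 16, n_iterations = 40, photons_per_eval = 1e4,
             final_photons_factor = 10, seed = seed, ...)
}

idx0 <- function() condition_preset("IDX0")
idx30 <- function() condition_preset("IDX30")
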