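test_that("the misfit is zero under exact self-consistency and grows off-truth", {
  p <- optical_properties(mu_s = 2, g = 0.9, n = 1.34)
  geom <- slab_geometry(1, 1)
  cfg <- fit_config(photons_per_eval = 5e3, seed = 31)
  # measurement generated noise-free with the same seed and photon count as
  # the objective evaluation: common random numbers give exactly zero
  m <- synth_measurement(p, geom, noise_free(), seed = cfg$seed + 104729L,
                         cfg = tally_config(n_photons = 5e3,
                                            seed = cfg$seed + 104729L))
  expect_identical(objective_misfit(c(2, 0.9), m, cfg), 0)
  # zero weights ignore mismatched observables
  cfg0 <- fit_config(weights = c(0, 0, 1e-12), photons_per_eval = 5e3,
                     seed = 31)
  cfg0$weights <- c(T = 0, R = 0, ang = 0.0)
  expect_identical(objective_misfit(c(50, 0.1), m, cfg0), 0)
  # misfit increases away from the generating truth
  expect_gt(objective_misfit(c(4, 0.9), m, cfg),
            objective_misfit(c(2, 0.9), m, cfg))
  # angular weight with no scan is a config error
  m2 <- m
  m2$angular <- list(edges_deg = numeric(1), fraction = numeric(0))
  expect_error(objective_misfit(c(2, 0.9), m2, cfg), "no angular scan")
})

test_that("PSO finds analytic minima, is deterministic, and its trace never rises", {
  sphere <- function(p) (p[1] - 3)^2 + (p[2] - 0.5)^2
  cfg <- fit_config(seed = 5)
  opt <- pso_minimize(sphere, c(0, 0), c(10, 1), cfg)
  expect_lt(max(abs(opt$par - c(3, 0.5))), 1e-3)
  expect_true(all(diff(opt$trace) <= 0))
  # determinism contract
  opt2 <- pso_minimize(sphere, c(0, 0), c(10, 1), cfg)
  expect_identical(opt$par, opt2$par)
  expect_identical(opt$trace, opt2$trace)
  # non-finite objective values are flagged and the particle resampled
  nasty <- function(p) if (p[1] < 5) NaN else (p[1] - 7)^2
  optn <- pso_minimize(nasty, c(0), c(10), fit_config(seed = 8))
  expect_true(is.finite(optn$value))
  expect_lt(abs(optn$par - 7), 0.1)
})

test_that("default-strength PSO solves 2-D Rastrigin in nearly every seed", {
  rastrigin <- function(p) 20 + sum(p^2 - 10 * cos(2 * pi * p))
  hits <- vapply(1:20, function(s) {
    cfg <- fit_config(n_particles = 40, n_iterations = 200, seed = s)
    pso_minimize(rastrigin, c(-2, -2), c(2, 2), cfg)$value
  }, numeric(1))
  expect_gte(mean(hits < 1.0), 0.95)
})

test_that("optical properties are recovered from a clean synthetic measurement", {
  p <- optical_properties(mu_s = 5, g = 0.9, n = 1.34)
  geom <- slab_geometry(1, 1)
  m <- synth_measurement(p, geom, noise_free(), seed = 17,
                         cfg = tally_config(n_photons = 1e5))
  fit <- fit_optical_properties(m, quick_fit_cfg(seed = 27))
  expect_lt(abs(fit$mu_s_hat - 5) / 5, 0.10)
  expect_lt(abs(fit$mu_s_prime_hat - 0.5) / 0.5, 0.15)
  expect_equal(fit$mu_s_prime_hat, fit$mu_s_hat * (1 - fit$g_hat))
  expect_true(all(diff(fit$trace) <= 0))
  # bit-reproducible for a fixed seed
  fit2 <- fit_optical_properties(m, quick_fit_cfg(seed = 27))
  expect_identical(fit$mu_s_hat, fit2$mu_s_hat)
  expect_identical(fit$trace, fit2$trace)
})

test_that("dropping the angular scan degrades anisotropy recovery", {
  # T and R alone constrain mainly mu_s(1-g); the angular scan carries the
  # anisotropy information
  p <- optical_properties(mu_s = 5, g = 0.9, n = 1.34)
  geom <- slab_geometry(1, 1)
  m <- synth_measurement(p, geom, noise_free(), seed = 17,
                         cfg = tally_config(n_photons = 1e5))
  full <- fit_optical_properties(m, quick_fit_cfg(seed = 33))
  tr_only_cfg <- quick_fit_cfg(seed = 33)
  tr_only_cfg$weights <- c(T = 1, R = 1, ang = 0)
  tr_only <- fit_optical_properties(m, tr_only_cfg)
  expect_gt(abs(tr_only$g_hat - 0.9), abs(full$g_hat - 0.9))
})
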