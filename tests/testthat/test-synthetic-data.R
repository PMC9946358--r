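test_that("condition presets embed the reported coefficient pairs", {
  p0 <- idx0()
  expect_equal(p0$mu_s, 11.76)
  expect_equal(p0$mu_s * (1 - p0$g), 0.164, tolerance = 0.0005 / 0.164)
  p30 <- idx30()
  expect_equal(p30$mu_s, 1.377)
  expect_equal(p30$mu_s * (1 - p30$g), 0.014, tolerance = 0.0005 / 0.014)
  # the ~10-fold reduction claim, as a >= 10 bound
  expect_gte(p0$mu_s_prime / p30$mu_s_prime, 10)
  expect_match(attr(p0, "provenance"), "derived")
})

test_that("synthetic measurements are deterministic and noise-free at zero noise", {
  geom <- slab_geometry(1, 1)
  p <- optical_properties(mu_s = 2, g = 0.8, n = 1.34)
  m1 <- synth_measurement(p, geom, noise_free(), seed = 5, cfg = quick_cfg(5e3))
  m2 <- synth_measurement(p, geom, noise_free(), seed = 5, cfg = quick_cfg(5e3))
  expect_identical(m1$T_total, m2$T_total)
  expect_identical(m1$angular$fraction, m2$angular$fraction)
  # zero noise: record equals the forward tallies exactly
  sim <- run_forward(p, geom, quick_cfg(5e3, seed = 5))
  expect_identical(m1$T_total, sim$T_total)
  expect_identical(m1$R_total, sim$R_total)
  expect_equal(m1$angular$fraction, sim$angular_hist$fraction)
  # truth metadata embedded (self-describing fixture)
  expect_equal(m1$meta$truth$mu_s, 2)
  expect_equal(m1$meta$truth$g, 0.8)
  expect_true(m1$meta$synthetic)
})

test_that("multiplicative noise has the configured coefficient of variation", {
  # noise applied to fixed tallies over many replicate seeds
  frac <- c(0.5, 0.3, 0.15, 0.05)
  noise <- noise_model(rel_sd_T = 0.01, rel_sd_R = 0.01, rel_sd_angular = 0.02)
  Ts <- vapply(1:200, function(s)
    inkoptics:::apply_measurement_noise(0.8, 0.1, frac, noise, s)$T_total,
    numeric(1))
  expect_equal(stats::sd(Ts) / mean(Ts), 0.01, tolerance = 0.002 / 0.01)
  # angular scans renormalize after noising
  one <- inkoptics:::apply_measurement_noise(0.8, 0.1, frac, noise, 3)
  expect_equal(sum(one$frac), 1, tolerance = 1e-12)
  # poisson mode produces a valid renormalized scan
  pois <- noise_model(mode = "poisson-counts", counts_scale = 1e4)
  two <- inkoptics:::apply_measurement_noise(0.8, 0.1, frac, pois, 4)
  expect_equal(sum(two$frac), 1, tolerance = 1e-12)
  expect_true(all(two$frac >= 0))
})

test_that("the fixture bundle is complete, self-describing and reproducible", {
  out1 <- file.path(tempdir(), "bundle1")
  out2 <- file.path(tempdir(), "bundle2")
  man1 <- make_fixture_bundle(out1, seed = 9, n_photons = 5e3)
  man2 <- make_fixture_bundle(out2, seed = 9, n_photons = 5e3)
  files <- vapply(man1$files, `[[`, character(1), "path")
  expect_true(all(file.exists(file.path(out1, files))))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  # every measurement lists its generating truth and loads cleanly
  for (f in grep("^measurement", files, value = TRUE)) {
    m <- load_measurement(file.path(out1, f))
    expect_s3_class(m, "measurement")
    expect_false(is.null(m$meta$truth))
  }
  # IDX0 fixture truth satisfies the reported coefficient pair
  m0 <- load_measurement(file.path(out1, "measurement_IDX0_clean.json"))
  expect_equal(m0$meta$truth$mu_s * (1 - m0$meta$truth$g), 0.164,
               tolerance = 0.0005 / 0.164)
  # byte-identical regeneration under the same seed
  for (f in files) {
    expect_identical(readBin(file.path(out1, f), "raw",
                             file.size(file.path(out1, f))),
                     readBin(file.path(out2, f), "raw",
                             file.size(file.path(out2, f))),
                     info = f)
  }
  unlink(c(out1, out2), recursive = TRUE)
})
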