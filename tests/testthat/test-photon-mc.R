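test_that("Henyey-Greenstein sampling matches its inverse CDF and first moment", {
  # isotropic inverse-CDF value
  expect_equal(sample_hg(0, 0.25), -0.5)
  # direct evaluation of the anisotropic inverse CDF
  g <- 0.9; u <- 0.5
  f <- (1 - g^2) / (1 - g + 2 * g * u)
  expect_equal(sample_hg(g, u), (1 + g^2 - f^2) / (2 * g), tolerance = 1e-12)
  expect_equal(round(sample_hg(0.9, 0.5), 5), 0.9855)
  # empirical mean equals g (HG first moment), 3 SE band
  withr::with_seed(7, {
    for (g in c(0, 0.5, 0.98)) {
      x <- sample_hg(g, stats::runif(2e5))
      expect_true(all(x >= -1 & x <= 1))
      se <- stats::sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - g), 3 * se)
    }
  })
  # g = 0 gives uniform deflection cosines
  withr::with_seed(2, {
    ks <- suppressWarnings(stats::ks.test(sample_hg(0, stats::runif(5e3)),
                                          "punif", -1, 1))
    expect_gt(ks$p.value, 0.01)
  })
  expect_error(sample_hg(1, 0.5), "strictly inside")
})

test_that("ballistic and specular limits reproduce their closed forms", {
  # matched transparent slab: free propagation
  p0 <- optical_properties(mu_s = 0, g = 0, mu_a = 0, n = 1)
  r0 <- run_forward(p0, slab_geometry(1, 1), quick_cfg(1e4, seed = 3))
  expect_identical(r0$T_total, 1)
  expect_identical(r0$R_total, 0)
  expect_identical(r0$A_total, 0)
  # Beer-Lambert for pure absorption across optical depths
  for (tau in c(0.5, 1, 2)) {
    p <- optical_properties(mu_s = 0, g = 0, mu_a = tau, n = 1)
    r <- run_forward(p, slab_geometry(1, 1), quick_cfg(5e4, seed = 3))
    expect_lt(abs(r$T_total - exp(-tau)), 3 * r$batch_se[["T"]])
    expect_equal(r$T_total + r$R_total + r$A_total, 1, tolerance = 1e-9)
  }
  # two-interface Fresnel slab: incoherent multiple reflections R = 2r/(1+r)
  pf <- optical_properties(mu_s = 0, g = 0, mu_a = 0, n = 1.5)
  rf <- run_forward(pf, slab_geometry(1, 1), quick_cfg(1e5, seed = 4))
  expect_lt(abs(rf$R_total - 2 * 0.04 / 1.04), 3 * rf$batch_se[["R"]])
  expect_gt(rf$R_specular, 0.03)  # entry face contributes ~r = 0.04
})

test_that("energy is conserved and tallies are reproducible across conditions", {
  geom <- slab_geometry(1, 1)
  for (mu_s in c(1.377, 11.76)) {
    for (g in c(0.5, 0.98605)) {
      p <- optical_properties(mu_s = mu_s, g = g, mu_a = 0.1, n = 1.34)
      r <- run_forward(p, geom, quick_cfg(2e4, seed = 11))
      se <- sqrt(r$batch_se[["T"]]^2 + r$batch_se[["R"]]^2)
      expect_lt(abs(r$T_total + r$R_total + r$A_total - 1), 3 * se + 1e-3)
      expect_true(all(c(r$T_total, r$R_total, r$A_total, r$R_specular) >= 0))
    }
  }
  # bit-identical tallies for identical (seed, cfg, props)
  p <- idx0()
  a <- run_forward(p, geom, quick_cfg(1e4, seed = 5))
  b <- run_forward(p, geom, quick_cfg(1e4, seed = 5))
  expect_identical(a$T_total, b$T_total)
  expect_identical(a$angular_hist$fraction, b$angular_hist$fraction)
  c2 <- run_forward(p, geom, quick_cfg(1e4, seed = 6))
  expect_false(identical(a$T_total, c2$T_total))
  # forward-dominated transport for near-unity anisotropy
  expect_gt(a$T_total, a$R_total)
})

test_that("the exit angular distribution is normalized and forward-ordered", {
  geom <- slab_geometry(1, 1)
  # ballistic-only: all transmitted weight in the 0-degree bin
  pb <- optical_properties(mu_s = 0, g = 0, mu_a = 0.5, n = 1)
  rb <- run_forward(pb, geom, quick_cfg(1e4, seed = 2))
  expect_equal(rb$angular_hist$fraction[1], 1)
  expect_equal(sum(rb$angular_hist$fraction), 1, tolerance = 1e-9)
  # lower-mu_s condition concentrates more weight at small angles
  r_hi <- run_forward(idx0(), geom, quick_cfg(5e4, seed = 9))
  r_lo <- run_forward(idx30(), geom, quick_cfg(5e4, seed = 9))
  expect_equal(sum(r_hi$angular_hist$fraction), 1, tolerance = 1e-9)
  cum5 <- function(r) sum(r$angular_hist$fraction[1:5])
  expect_gt(cum5(r_lo), cum5(r_hi))
  # accessor: data frame with solid-angle option
  d <- angular_distribution(r_hi)
  expect_equal(nrow(d), 90)
  expect_equal(sum(d$fraction), 1, tolerance = 1e-9)
  dsr <- angular_distribution(r_hi, per_solid_angle = TRUE)
  expect_true(all(dsr$fraction >= 0))
  # zero transmission sentinel
  pz <- optical_properties(mu_s = 0, g = 0, mu_a = 40, n = 1)
  rz <- run_forward(pz, geom, quick_cfg(2e3, seed = 2))
  expect_equal(nrow(angular_distribution(rz)), 0)
})

test_that("PSF kernels normalize, stay centered, and widen with depth", {
  geom <- slab_geometry(1, 1)
  depths <- c(50, 150, 250)
  # no scattering: every kernel is a central unit impulse
  p0 <- optical_properties(mu_s = 0, g = 0, mu_a = 0.2, n = 1)
  s0 <- psf_stack(p0, geom, quick_cfg(2e3, seed = 4, depth_slices = depths))
  for (k in s0$kernels) {
    expect_equal(sum(k), 1, tolerance = 1e-9)
    centre <- (nrow(k) + 1) / 2
    expect_equal(k[centre, centre], 1)
  }
  expect_equal(unname(psf_rms_radius(s0)), c(0, 0, 0))
  # scattering: kernels normalized, RMS radius nondecreasing with depth,
  # approximate x/y mirror symmetry
  s1 <- psf_stack(idx0(), geom, quick_cfg(5e4, seed = 8, depth_slices = depths))
  for (k in s1$kernels) expect_equal(sum(k), 1, tolerance = 1e-9)
  r1 <- psf_rms_radius(s1)
  expect_true(all(diff(r1) >= 0))
  k <- s1$kernels[[3]]
  expect_lt(sum(abs(k - k[nrow(k):1, ])) / 2, 0.1)
  expect_lt(sum(abs(k - k[, ncol(k):1])) / 2, 0.1)
  # matched seeds: the index-matched condition has strictly narrower kernels
  s2 <- psf_stack(idx30(), geom, quick_cfg(5e4, seed = 8, depth_slices = depths))
  expect_true(all(psf_rms_radius(s2) < r1))
  expect_error(psf_stack(idx0(), geom, quick_cfg(1e3, depth_slices = 1500)),
               "inside the slab")
})
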