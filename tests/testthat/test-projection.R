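test_that("the spoke pattern has the designed symmetry, duty cycle and gap width", {
  n_spokes <- 12
  p <- make_spoke_pattern(n_spokes = n_spokes, diameter = 2000, pitch = 5)
  g <- p$grid
  n <- nrow(g)
  c0 <- (n + 1) / 2
  xy <- (seq_len(n) - c0) * p$pitch
  rr <- sqrt(outer(xy^2, xy^2, `+`))
  inside <- t(rr) <= 1000  # rr is symmetric; orientation irrelevant
  # duty cycle 0.5 inside the disk
  expect_equal(mean(g[inside]), 0.5, tolerance = 0.02)
  # rotation by one spoke period maps the pattern onto itself
  theta <- 2 * pi / n_spokes
  xm <- matrix(xy, n, n, byrow = TRUE); ym <- matrix(xy, n, n)
  xr <- cos(theta) * xm - sin(theta) * ym
  yr <- sin(theta) * xm + cos(theta) * ym
  ir <- pmin(pmax(round(yr / p$pitch + c0), 1), n)
  jr <- pmin(pmax(round(xr / p$pitch + c0), 1), n)
  rotated <- matrix(g[cbind(as.vector(ir), as.vector(jr))], n, n)
  # compare away from the hub, the rim, and the sector boundaries, where
  # nearest-neighbour resampling of the test rotation is itself inexact
  rmat <- sqrt(xm^2 + ym^2)
  sector_width <- pi / n_spokes
  ang_off <- (atan2(ym, xm) %% sector_width)
  d_boundary <- pmin(ang_off, sector_width - ang_off) * rmat
  core <- rmat > 50 & rmat < 980 & d_boundary > 2 * p$pitch
  expect_gt(mean(rotated[core] == g[core]), 0.99)
  # gap arc width at r = 200 um is pi * 200 / 12 ~ 52.4 um: along the circle
  # of radius 200 um the lit fraction is 0.5 in arcs of that length
  r0 <- 200
  ang <- seq(0, 2 * pi, length.out = 4096)[-1]
  px <- round(r0 * cos(ang) / p$pitch + c0)
  py <- round(r0 * sin(ang) / p$pitch + c0)
  ring <- g[cbind(py, px)]
  runs <- rle(ring)
  arc_um <- mean(runs$lengths[runs$values == 0]) * (2 * pi * r0 / 4096)
  expect_equal(arc_um, pi * 200 / 12, tolerance = 0.08)
  expect_error(make_spoke_pattern(12, diameter = 10, pitch = 5), "4 pixels")
})

test_that("line-pair blocks have half-period bars at duty cycle 0.5", {
  p <- make_line_pairs(c(40, 80), pitch = 5, n_bars = 6)
  blocks <- attr(p, "blocks")
  expect_equal(nrow(blocks), 2)
  for (i in 1:2) {
    block <- p$grid[, blocks$col_lo[i]:blocks$col_hi[i]]
    interior <- block[11:50, ]
    expect_equal(mean(interior), 0.5, tolerance = 5 / (6 * blocks$period[i]))
    # bar width = period / 2
    row <- interior[1, ]
    runs <- rle(row)
    expect_equal(mean(runs$lengths[runs$values == 1]) * p$pitch,
                 blocks$period[i] / 2, tolerance = 5)
  }
  # a single period is a square-wave grating (brute-force pixel check)
  p1 <- make_line_pairs(40, pitch = 5, n_bars = 4, height_px = 8,
                        gutter_px = 0)
  x <- (seq_len(ncol(p1$grid)) - 0.5) * 5
  expect_equal(p1$grid[4, ], as.numeric((x %% 40) < 20))
  expect_error(make_line_pairs(8, pitch = 5), "periods")
})

test_that("blurring conserves intensity and matches the direct-sum oracle", {
  pat <- make_line_pairs(100, pitch = 5, n_bars = 4, height_px = 12,
                         gutter_px = 4)
  k <- gaussian_kernel(20, pitch = 5)
  bf <- blur_pattern(pat, k, method = "fft")
  bd <- blur_pattern(pat, k, method = "direct")
  expect_lt(max(abs(bf$grid - bd$grid)), 1e-6)
  expect_equal(sum(bf$grid), sum(pat$grid), tolerance = 1e-6)
  # unit impulse kernel: identity (up to zero padding)
  ki <- matrix(0, 3, 3); ki[2, 2] <- 1
  bi <- blur_pattern(pat, ki)
  expect_equal(bi$grid[2:(nrow(pat$grid) + 1), 2:(ncol(pat$grid) + 1)],
               pat$grid, tolerance = 1e-9)
})

test_that("Gaussian blur of a sinusoidal grating reproduces the MTF attenuation", {
  # closed form: contrast of a sine grating after Gaussian blur is
  # exp(-2 pi^2 sigma^2 / p^2)
  sigma <- 20; period <- 100
  pat <- make_sine_grating(period, pitch = 2.5, n_periods = 10)
  blurred <- blur_pattern(pat, gaussian_kernel(sigma, pitch = 2.5))
  rk <- (nrow(blurred$grid) - nrow(pat$grid)) %/% 2
  ck <- (ncol(blurred$grid) - ncol(pat$grid)) %/% 2
  # central row, central half of the columns (away from roll-off)
  cols <- ck + seq(as.integer(0.25 * ncol(pat$grid)),
                   as.integer(0.75 * ncol(pat$grid)))
  prof <- blurred$grid[rk + nrow(pat$grid) %/% 2, cols]
  expect_equal(michelson_contrast(prof),
               exp(-2 * pi^2 * sigma^2 / period^2), tolerance = 0.02)
})

test_that("contrast decreases with kernel width and the ladder metric matches its oracle", {
  # monotone contrast loss over a sigma sweep
  pat <- make_sine_grating(100, pitch = 2.5, n_periods = 8)
  contrasts <- vapply(c(5, 10, 20, 40), function(s) {
    b <- blur_pattern(pat, gaussian_kernel(s, pitch = 2.5))
    rk <- (nrow(b$grid) - nrow(pat$grid)) %/% 2
    ck <- (ncol(b$grid) - ncol(pat$grid)) %/% 2
    cols <- ck + seq(as.integer(0.25 * ncol(pat$grid)),
                     as.integer(0.75 * ncol(pat$grid)))
    michelson_contrast(b$grid[rk + nrow(pat$grid) %/% 2, cols])
  }, numeric(1))
  expect_true(all(diff(contrasts) < 0))

  # impulse kernel resolves the smallest ladder feature
  ki <- matrix(0, 3, 3); ki[2, 2] <- 1
  attr(ki, "pitch") <- 5
  rep_i <- resolution_at_depth(NULL, kernel = ki, threshold = 0.1,
                               periods = c(20, 40, 80), pitch = 5)
  expect_equal(rep_i$min_resolved, 10)
  # very wide kernel: unresolved sentinel
  kw <- gaussian_kernel(600, pitch = 5, radius_sigmas = 2)
  rep_w <- resolution_at_depth(NULL, kernel = kw, threshold = 0.1,
                               periods = c(20, 40, 80), pitch = 5)
  expect_false(rep_w$resolved)
  expect_identical(rep_w$min_resolved, Inf)

  # Gaussian kernel vs closed-form square-wave contrast (odd harmonics 1, 3)
  sigma <- 20; threshold <- 0.1
  periods <- c(20, 30, 40, 60, 80, 100, 150, 200)
  closed_contrast <- vapply(periods, function(p) {
    a1 <- exp(-2 * pi^2 * sigma^2 / p^2)
    a3 <- exp(-2 * pi^2 * (3 * sigma)^2 / p^2)
    num <- (4 / pi) * (a1 - a3 / 3)  # peak-to-mean of blurred square wave
    min(1, num)
  }, numeric(1))
  oracle_min <- min(periods[closed_contrast >= threshold]) / 2
  kg <- gaussian_kernel(sigma, pitch = 2.5)
  rep_g <- resolution_at_depth(NULL, kernel = kg, threshold = threshold,
                               periods = periods, pitch = 2.5)
  expect_equal(rep_g$min_resolved, oracle_min)
})

test_that("print-mask thresholding and pattern round trips behave", {
  pat <- make_spoke_pattern(8, diameter = 500, pitch = 5)
  mask <- threshold_print_mask(pat, rel = 0.5)
  expect_identical(mask$grid, pat$grid)
  snow <- make_snowflake_pattern(diameter = 800, pitch = 10, stroke = 60)
  expect_true(all(snow$grid %in% c(0, 1)))
  expect_gt(sum(snow$grid), 0)
})
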