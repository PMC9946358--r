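#' Projection pattern image
#'
#' A 2D nonnegative intensity grid with a physical pixel pitch, the unit the
#' blurring stage consumes and produces. Image origin is top-left, x
#' rightward (columns), y downward (rows).
#'
#' @param grid Numeric matrix of finite, nonnegative intensities.
#' @param pitch Micrometres per pixel (> 0).
#' @param normalization `"binary"` (values restricted to 0/1) or
#'   `"relative"`.
#' @return An object of class `pattern_image`.
#' @export
pattern_image <- function(grid, pitch,
                          normalization = c("relative", "binary")) {
  normalization <- match.arg(normalization)
  grid <- as.matrix(grid)
  stopifnot(is.numeric(grid), all(is.finite(grid)), all(grid >= 0),
            pitch > 0)
  if (normalization == "binary" && !all(grid %in% c(0, 1)))
    stop("binary patterns may contain only 0 and 1")
  structure(list(grid = grid, pitch = pitch, normalization = normalization),
            class = "pattern_image")
}

#' @export
print.pattern_image <- function(x, ...) {
  cat(sprintf("Pattern: %d x %d px at %g um/px (%s), %.3g um x %.3g um\n",
              nrow(x$grid), ncol(x$grid), x$pitch, x$normalization,
              nrow(x$grid) * x$pitch, ncol(x$grid) * x$pitch))
  invisible(x)
}

#' Spoke (Siemens-star-like) binary test pattern
#'
#' A wheel of `n_spokes` equal lit wedges alternating with equal gaps
#' (angular duty cycle 0.5), the classic target whose local feature size
#' shrinks linearly toward the hub: the gap arc width at radius `r` is
#' `pi * r / n_spokes`.
#'
#' @param n_spokes Number of lit wedges (>= 2).
#' @param diameter Wheel diameter in micrometres.
#' @param pitch Micrometres per pixel.
#' @param margin Extra blank border in micrometres.
#' @return A binary [pattern_image()].
#' @export
make_spoke_pattern <- function(n_spokes = 12, diameter = 2000, pitch = 5,
                               margin = 0) {
  stopifnot(n_spokes >= 2, diameter > 0, pitch > 0)
  if (diameter < 4 * pitch) stop("diameter must span at least 4 pixels")
  half <- diameter / 2 + margin
  n <- 2L * ceiling(half / pitch) + 1L
  c0 <- (n + 1) / 2
  xy <- (seq_len(n) - c0) * pitch
  xm <- matrix(xy, n, n, byrow = TRUE)   # x along columns
  ym <- matrix(xy, n, n)                 # y along rows
  r <- sqrt(xm^2 + ym^2)
  theta <- atan2(ym, xm) %% (2 * pi)
  sector <- floor(theta / (pi / n_spokes))
  grid <- (r <= diameter / 2) * (sector %% 2 == 0)
  pattern_image(grid * 1, pitch, "binary")
}

#' Line-pair (bar target) ladder pattern
#'
#' One block of vertical bars per requested period, duty cycle 0.5, laid out
#' side by side with blank gutters — the quantification target for the
#' resolvable-feature metric (feature size = half period).
#'
#' @param periods Bar periods in micrometres (each >= 2 * pitch).
#' @param pitch Micrometres per pixel.
#' @param n_bars Bars per block.
#' @param height_px Block height in pixels.
#' @param gutter_px Blank columns between blocks and at the outer border.
#' @return A binary [pattern_image()] with a `blocks` attribute (data frame:
#'   `period`, `col_lo`, `col_hi` in pixel indices).
#' @export
make_line_pairs <- function(periods, pitch = 5, n_bars = 6, height_px = 40,
                            gutter_px = 10) {
  stopifnot(length(periods) >= 1, all(periods >= 2 * pitch), pitch > 0)
  widths <- vapply(periods, function(p) as.integer(round(n_bars * p / pitch)),
                   integer(1))
  ncol_tot <- sum(widths) + gutter_px * (length(periods) + 1L)
  nrow_tot <- height_px + 2L * gutter_px
  grid <- matrix(0, nrow_tot, ncol_tot)
  blocks <- data.frame(period = periods, col_lo = NA_integer_,
                       col_hi = NA_integer_)
  col <- gutter_px
  rows <- gutter_px + seq_len(height_px)
  for (i in seq_along(periods)) {
    w <- widths[i]
    x <- (seq_len(w) - 0.5) * pitch
    bar <- (x %% periods[i]) < periods[i] / 2
    grid[rows, col + seq_len(w)] <- rep(bar * 1, each = length(rows))
    blocks$col_lo[i] <- col + 1L
    blocks$col_hi[i] <- col + w
    col <- col + w + gutter_px
  }
  out <- pattern_image(grid, pitch, "binary")
  attr(out, "blocks") <- blocks
  out
}

#' Sinusoidal grating pattern
#'
#' Intensity `0.5 + 0.5 sin(2 pi x / period)`; under convolution with a
#' normalized kernel its Michelson contrast is attenuated exactly by the
#' kernel's modulation transfer at the grating frequency (for a Gaussian of
#' width sigma: `exp(-2 pi^2 sigma^2 / period^2)`), which makes it the
#' analytic oracle for the blurring stage.
#'
#' @param period Grating period in micrometres.
#' @param pitch Micrometres per pixel.
#' @param n_periods Number of periods across the grating.
#' @param height_px Rows.
#' @return A [pattern_image()].
#' @export
make_sine_grating <- function(period, pitch = 2.5, n_periods = 10,
                              height_px = 32) {
  stopifnot(period >= 4 * pitch)
  w <- as.integer(round(n_periods * period / pitch))
  x <- (seq_len(w) - 0.5) * pitch
  row <- 0.5 + 0.5 * sin(2 * pi * x / period)
  pattern_image(matrix(rep(row, each = height_px), height_px, w), pitch)
}

#' Snowflake-like branched test pattern
#'
#' A six-fold rotationally replicated branched polyline, rasterized with a
#' given stroke width. Cosmetic companion to [make_spoke_pattern()]; the
#' branch geometry is decorative and carries no quantitative meaning.
#'
#' @param diameter Overall diameter in micrometres.
#' @param pitch Micrometres per pixel.
#' @param stroke Stroke width in micrometres.
#' @return A binary [pattern_image()].
#' @export
make_snowflake_pattern <- function(diameter = 2000, pitch = 5, stroke = 60) {
  half <- diameter / 2
  n <- 2L * ceiling(half / pitch) + 1L
  c0 <- (n + 1) / 2
  xy <- (seq_len(n) - c0) * pitch
  xm <- matrix(xy, n, n, byrow = TRUE)
  ym <- matrix(xy, n, n)
  segs <- list(c(0, 0, half, 0),
               c(0.5 * half, 0, 0.5 * half + 0.25 * half * cos(pi / 3),
                 0.25 * half * sin(pi / 3)),
               c(0.5 * half, 0, 0.5 * half + 0.25 * half * cos(-pi / 3),
                 0.25 * half * sin(-pi / 3)),
               c(0.75 * half, 0, 0.75 * half + 0.15 * half * cos(pi / 3),
                 0.15 * half * sin(pi / 3)),
               c(0.75 * half, 0, 0.75 * half + 0.15 * half * cos(-pi / 3),
                 0.15 * half * sin(-pi / 3)))
  grid <- matrix(FALSE, n, n)
  for (k in 0:5) {
    a <- k * pi / 3
    ca <- cos(a); sa <- sin(a)
    for (s in segs) {
      x1 <- ca * s[1] - sa * s[2]; y1 <- sa * s[1] + ca * s[2]
      x2 <- ca * s[3] - sa * s[4]; y2 <- sa * s[3] + ca * s[4]
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx^2 + dy^2
      t <- pmin(1, pmax(0, ((xm - x1) * dx + (ym - y1) * dy) / len2))
      d2 <- (xm - (x1 + t * dx))^2 + (ym - (y1 + t * dy))^2
      grid <- grid | (d2 <= (stroke / 2)^2)
    }
  }
  pattern_image(grid * 1, pitch, "binary")
}

#' Discrete Gaussian blur kernel
#'
#' @param sigma Gaussian width in micrometres.
#' @param pitch Micrometres per cell.
#' @param radius_sigmas Kernel half-width in units of sigma.
#' @return A unit-sum square matrix with odd side, `pitch` attached as an
#'   attribute.
#' @export
gaussian_kernel <- function(sigma, pitch, radius_sigmas = 4) {
  stopifnot(sigma > 0, pitch > 0)
  r <- max(1L, ceiling(radius_sigmas * sigma / pitch))
  xy <- (-r:r) * pitch
  k <- exp(-outer(xy^2, xy^2, `+`) / (2 * sigma^2))
  k <- k / sum(k)
  attr(k, "pitch") <- pitch
  k
}

# Full linear 2D convolution via zero-padded FFT.
conv2_fft <- function(a, k) {
  nr <- nrow(a) + nrow(k) - 1L
  nc <- ncol(a) + ncol(k) - 1L
  nr2 <- stats::nextn(nr, c(2, 3, 5))
  nc2 <- stats::nextn(nc, c(2, 3, 5))
  pa <- matrix(0, nr2, nc2); pa[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  pk <- matrix(0, nr2, nc2); pk[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  out <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) /
    (nr2 * nc2)
  out[seq_len(nr), seq_len(nc)]
}

# Direct-sum full linear 2D convolution; O(N^2 M^2) reference path.
conv2_direct <- function(a, k) {
  nr <- nrow(a) + nrow(k) - 1L
  nc <- ncol(a) + ncol(k) - 1L
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      if (k[i, j] == 0) next
      out[(i - 1L) + seq_len(nrow(a)), (j - 1L) + seq_len(ncol(a))] <-
        out[(i - 1L) + seq_len(nrow(a)), (j - 1L) + seq_len(ncol(a))] +
        k[i, j] * a
    }
  }
  out
}

# Resample a kernel defined on pitch_in onto pitch_out by bilinear
# interpolation on physical coordinates, then renormalize to unit sum.
resample_kernel <- function(k, pitch_in, pitch_out) {
  if (abs(pitch_in - pitch_out) < 1e-9) return(k)
  half_in <- (nrow(k) - 1) / 2 * pitch_in
  r_out <- ceiling(half_in / pitch_out)
  xo <- (-r_out:r_out) * pitch_out
  idx <- xo / pitch_in + (nrow(k) + 1) / 2   # fractional source index
  lo <- pmin(pmax(floor(idx), 1), nrow(k))
  hi <- pmin(lo + 1, nrow(k))
  wf <- idx - lo
  interp_1d <- function(m) {  # interpolate rows of m at idx
    m[lo, , drop = FALSE] * (1 - wf) + m[hi, , drop = FALSE] * wf
  }
  out <- t(interp_1d(t(interp_1d(k))))
  out[out < 0] <- 0
  s <- sum(out)
  if (s <= 0) stop("kernel resampling produced an empty kernel")
  out / s
}

#' Blur a pattern with an arbitrary normalized kernel
#'
#' Full (zero-padded) linear convolution: the output grid grows by the
#' kernel radius on every side, so total intensity is conserved exactly up
#' to numerical precision.
#'
#' @param pattern A [pattern_image()].
#' @param kernel Unit-sum matrix; a `pitch` attribute (um/cell) triggers
#'   resampling onto the pattern pitch when the two differ.
#' @param method `"fft"` (default) or `"direct"` (reference path).
#' @return A [pattern_image()] with normalization `"relative"`.
#' @export
blur_pattern <- function(pattern, kernel, method = c("fft", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(pattern, "pattern_image"))
  kp <- attr(kernel, "pitch")
  if (!is.null(kp)) kernel <- resample_kernel(kernel, kp, pattern$pitch)
  kernel <- unclass(as.matrix(kernel))
  out <- if (method == "fft") conv2_fft(pattern$grid, kernel)
         else conv2_direct(pattern$grid, kernel)
  out[out < 0] <- 0
  pattern_image(out, pattern$pitch, "relative")
}

#' Blur a pattern with the PSF at a given depth
#'
#' Selects the PSF slice nearest to `depth` (within half a slice spacing)
#' and convolves, predicting the light pattern a collimated projection
#' produces at that depth inside the bioink.
#'
#' @param pattern A [pattern_image()].
#' @param psf A `psf_stack` from [psf_stack()].
#' @param depth Depth in micrometres.
#' @param method Convolution path, as in [blur_pattern()].
#' @return A blurred [pattern_image()].
#' @export
blur_at_depth <- function(pattern, psf, depth, method = c("fft", "direct")) {
  stopifnot(inherits(psf, "psf_stack"))
  i <- which.min(abs(psf$depths - depth))
  spacing <- if (length(psf$depths) > 1) min(diff(sort(psf$depths)))
             else 2 * abs(psf$depths - depth) + 1
  if (abs(psf$depths[i] - depth) > spacing / 2 + 1e-9)
    stop(sprintf("no PSF slice within half a slice spacing of %g um", depth))
  k <- psf$kernels[[i]]
  attr(k, "pitch") <- psf$pitch
  blur_pattern(pattern, k, method)
}

#' Michelson contrast of an intensity profile
#'
#' @param profile Numeric vector of nonnegative intensities.
#' @return `(max - min) / (max + min)`, or 0 for an all-zero profile.
#' @export
michelson_contrast <- function(profile) {
  mx <- max(profile); mn <- min(profile)
  if (mx + mn == 0) return(0)
  (mx - mn) / (mx + mn)
}

#' Resolvable feature size at a given depth
#'
#' Blurs one bar-target block per ladder period with the depth's PSF slice,
#' measures the Michelson contrast of the central row (restricted to the
#' central bars, away from block edges) and reports the smallest feature
#' (half period) whose contrast meets the threshold.
#'
#' @param psf A `psf_stack`.
#' @param depth Depth in micrometres.
#' @param threshold Contrast cutoff in (0, 1); default 0.1.
#' @param periods Ladder periods in micrometres.
#' @param kernel Optional explicit kernel (with `pitch` attribute) used
#'   instead of the PSF slice — the hook for analytic-kernel oracles.
#' @param pitch Pattern pitch in micrometres.
#' @return An object of class `resolution_report`: `depth`, `threshold`,
#'   `contrast_by_feature` (data frame with `period`, `feature`, `contrast`),
#'   and `min_resolved` (um; `Inf` with `resolved = FALSE` when no ladder
#'   feature meets the threshold).
#' @export
resolution_at_depth <- function(psf, depth = NULL, threshold = 0.1,
                                periods = c(20, 30, 40, 60, 80, 100,
                                            150, 200, 300, 400),
                                kernel = NULL, pitch = 5) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(kernel)) {
    stopifnot(inherits(psf, "psf_stack"), !is.null(depth))
    i <- which.min(abs(psf$depths - depth))
    kernel <- psf$kernels[[i]]
    attr(kernel, "pitch") <- psf$pitch
    depth <- psf$depths[i]
  }
  # physical kernel half-width; the bar block must extend beyond it so that
  # block-edge roll-off cannot masquerade as bar modulation in the centre
  kp <- attr(kernel, "pitch")
  if (is.null(kp)) kp <- pitch
  k_half_um <- (max(dim(as.matrix(kernel))) - 1) / 2 * kp
  contrast <- vapply(periods, function(p) {
    n_bars <- max(6L, ceiling(2 * (k_half_um + 2 * p) / p))
    block <- make_line_pairs(p, pitch = pitch, n_bars = n_bars,
                             height_px = 24, gutter_px = 2)
    blurred <- blur_pattern(block, kernel)
    rk <- (nrow(blurred$grid) - nrow(block$grid)) %/% 2
    ck <- (ncol(blurred$grid) - ncol(block$grid)) %/% 2
    blk <- attr(block, "blocks")
    centre <- ck + (blk$col_lo + blk$col_hi) / 2
    half_win <- as.integer(round(p / pitch))  # one period each way
    cols <- as.integer(round(centre - half_win)):as.integer(round(centre + half_win))
    row <- blurred$grid[rk + 2L + 12L, cols]
    michelson_contrast(row)
  }, numeric(1))
  tab <- data.frame(period = periods, feature = periods / 2,
                    contrast = contrast)
  ok <- tab$contrast >= threshold
  min_resolved <- if (any(ok)) min(tab$feature[ok]) else Inf
  structure(list(depth = depth, threshold = threshold,
                 contrast_by_feature = tab, min_resolved = min_resolved,
                 resolved = any(ok)),
            class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf("Resolution at %g um depth (contrast threshold %g):\n",
              x$depth, x$threshold))
  if (is.finite(x$min_resolved))
    cat(sprintf("  smallest resolved feature: %g um\n", x$min_resolved))
  else cat("  unresolved at every ladder feature\n")
  invisible(x)
}

#' Threshold a blurred dose pattern into a predicted printed mask
#'
#' Relative-threshold surrogate for the gel point: pixels receiving at least
#' `rel` times the unblurred lit-region intensity are marked printed.
#' Photopolymerization kinetics are out of scope; this is a purely optical
#' criterion.
#'
#' @param pattern A blurred [pattern_image()].
#' @param rel Relative threshold in (0, 1), default 0.5.
#' @param reference Reference intensity (default: 1, the unblurred lit
#'   level of a binary pattern).
#' @return A binary [pattern_image()].
#' @export
threshold_print_mask <- function(pattern, rel = 0.5, reference = 1) {
  stopifnot(inherits(pattern, "pattern_image"), rel > 0, rel < 1)
  pattern_image((pattern$grid >= rel * reference) * 1, pattern$pitch,
                "binary")
}
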