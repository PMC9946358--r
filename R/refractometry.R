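#' Critical angle of total internal reflection
#'
#' Angle beyond which light travelling in the high-index prism is totally
#' reflected at the prism-sample interface: `asin(n_sample / n_prism)`.
#'
#' @param n_sample Sample index, `1 <= n_sample < n_prism`.
#' @param n_prism Prism index; 1.8421 is N-SF11 glass at 405 nm.
#' @return Critical angle in degrees.
#' @examples
#' critical_angle_deg(1.3330)  # ~46.35 degrees
#' @export
critical_angle_deg <- function(n_sample, n_prism = 1.8421) {
  if (any(n_sample < 1)) stop("n_sample must be >= 1")
  if (any(n_sample >= n_prism))
    stop("n_sample must be below the prism index (no TIR otherwise)")
  asin(n_sample / n_prism) * 180 / pi
}

#' Sample index from a critical angle
#'
#' Exact inverse of [critical_angle_deg()]: `n = n_prism * sin(theta_c)`.
#'
#' @param theta_c_deg Critical angle in degrees, inside (0, 90).
#' @param n_prism Prism index.
#' @return Sample refractive index.
#' @export
index_from_angle <- function(theta_c_deg, n_prism = 1.8421) {
  if (any(theta_c_deg <= 0) || any(theta_c_deg >= 90))
    stop("critical angle must lie strictly inside (0, 90) degrees")
  n_prism * sin(theta_c_deg * pi / 180)
}

#' Two-standard refractometer calibration
#'
#' Relates the total-internal-reflection boundary position on the camera to
#' the actual reflecting angle. Each standard's known index is converted to
#' its critical angle and the unique line through the two (pixel, angle)
#' points is fitted. The pixel-to-angle map is taken as linear, consistent
#' with the small-angle collimating-lens geometry of the instrument; two
#' standards determine exactly a line.
#'
#' @param standards Data frame (or 2-column matrix) with columns `pixel` and
#'   `n`: boundary position and known refractive index of two calibration
#'   liquids (typically water and isopropanol at 405 nm, values taken from an
#'   index database — they are inputs, not package constants).
#' @param n_prism Prism index (N-SF11 at 405 nm by default).
#' @return An object of class `refractometer_calibration` with the fitted
#'   `map` (`intercept`, `slope`; angle in degrees as a function of pixel).
#' @export
refractometer_calibration <- function(standards, n_prism = 1.8421) {
  standards <- as.data.frame(standards)
  stopifnot(nrow(standards) == 2L,
            all(c("pixel", "n") %in% names(standards)))
  if (standards$pixel[1] == standards$pixel[2])
    stop("standard boundary positions must be distinct")
  if (any(standards$n >= n_prism))
    stop("standard indices must be below the prism index")
  theta <- critical_angle_deg(standards$n, n_prism)
  slope <- diff(theta) / diff(standards$pixel)
  intercept <- theta[1] - slope * standards$pixel[1]
  if (slope == 0) stop("degenerate calibration: identical critical angles")
  structure(list(n_prism = n_prism,
                 standards = standards[order(standards$pixel), ],
                 map = c(intercept = intercept, slope = slope)),
            class = "refractometer_calibration")
}

#' @export
print.refractometer_calibration <- function(x, ...) {
  cat(sprintf("Refractometer calibration (prism n = %g)\n", x$n_prism))
  cat(sprintf("  angle[deg] = %.6g + %.6g * pixel\n",
              x$map["intercept"], x$map["slope"]))
  invisible(x)
}

#' Refractive index from a TIR boundary position
#'
#' Maps a boundary pixel position through the calibrated linear pixel-to-
#' angle map and inverts Snell's law at the critical angle:
#' `n = n_prism * sin(theta_c)`.
#'
#' @param pixel Boundary position in pixels.
#' @param cal A [refractometer_calibration()].
#' @param window_frac Allowed extrapolation beyond the standards' pixel span,
#'   as a fraction of that span (default 0.5).
#' @return Sample refractive index.
#' @examples
#' cal <- refractometer_calibration(
#'   data.frame(pixel = c(200, 800), n = c(1.3330, 1.3776)))
#' index_from_boundary(500, cal)
#' @export
index_from_boundary <- function(pixel, cal, window_frac = 0.5) {
  stopifnot(inherits(cal, "refractometer_calibration"))
  px <- cal$standards$pixel
  span <- diff(range(px))
  lo <- min(px) - window_frac * span
  hi <- max(px) + window_frac * span
  if (any(pixel < lo) || any(pixel > hi))
    stop(sprintf("pixel outside the calibrated window [%g, %g]", lo, hi))
  theta <- cal$map["intercept"] + cal$map["slope"] * pixel
  if (any(theta <= 0) || any(theta >= 90))
    stop("mapped angle outside (0, 90) degrees")
  unname(index_from_angle(theta, cal$n_prism))
}
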