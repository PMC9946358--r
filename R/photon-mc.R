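#' Plane-parallel slab geometry
#'
#' A bare bioink slab with the same ambient medium on both faces. Cuvette or
#' coverslip glass is not modelled; the ambient defaults to air so that exit
#' angles match a goniometer measurement taken in air.
#'
#' @param thickness Slab thickness in mm (> 0); 1 mm matches the
#'   integrating-sphere samples the inverse stage targets.
#' @param n_ambient Refractive index of the surrounding medium (>= 1).
#' @param wavelength Working wavelength in nm; metadata only, no dispersion
#'   model is applied.
#' @return An object of class `slab_geometry`.
#' @export
slab_geometry <- function(thickness = 1, n_ambient = 1, wavelength = 405) {
  stopifnot(is.numeric(thickness), thickness > 0, is.finite(thickness),
            is.numeric(n_ambient), n_ambient >= 1)
  structure(list(thickness = thickness, n_ambient = n_ambient,
                 wavelength = wavelength),
            class = "slab_geometry")
}

#' Monte Carlo tally configuration
#'
#' @param n_photons Number of photon packets (>= 1). 1e6 is used for reported
#'   runs; tests and inverse-fit evaluations use fewer.
#' @param seed Integer seed; together with the configuration it determines the
#'   tallies bit-for-bit.
#' @param angular_bin_deg Width of the exit-angle histogram bins over
#'   `[0, 90)` degrees.
#' @param lateral_pitch Point-spread-function grid pitch in micrometres.
#' @param lateral_extent Half-width of the PSF grid in micrometres; weight
#'   landing outside is tracked separately and the kernels renormalized.
#' @param depth_slices Depth planes (micrometres, inside the slab) at which
#'   lateral spread kernels are tallied; `NULL` disables PSF accumulation.
#' @param roulette_threshold,roulette_survival Russian-roulette weight
#'   threshold and survival probability (survivors are reweighted by
#'   `1 / roulette_survival`).
#' @param n_batches Number of equal photon batches used for the standard
#'   errors of T and R.
#' @return An object of class `tally_config`.
#' @export
tally_config <- function(n_photons = 1e6, seed = 1, angular_bin_deg = 1,
                         lateral_pitch = 5, lateral_extent = 300,
                         depth_slices = NULL, roulette_threshold = 1e-4,
                         roulette_survival = 0.1, n_batches = 10) {
  stopifnot(n_photons >= 1, angular_bin_deg > 0, angular_bin_deg <= 90,
            lateral_pitch > 0, lateral_extent >= lateral_pitch,
            roulette_threshold > 0, roulette_survival > 0,
            roulette_survival <= 1, n_batches >= 2)
  if (!is.null(depth_slices)) {
    stopifnot(length(depth_slices) >= 1, all(depth_slices > 0))
    depth_slices <- sort(unique(as.numeric(depth_slices)))
  }
  structure(list(n_photons = as.numeric(n_photons), seed = as.integer(seed),
                 angular_bin_deg = angular_bin_deg,
                 lateral_pitch = lateral_pitch,
                 lateral_extent = lateral_extent, depth_slices = depth_slices,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 n_batches = as.integer(n_batches)),
            class = "tally_config")
}

#' Sample the Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function, the standard
#' one-parameter model for forward-peaked scattering in tissue optics. Its
#' mean cosine equals the anisotropy `g`.
#'
#' @param g Anisotropy, strictly inside (-1, 1).
#' @param u Uniform variates in `[0, 1)`.
#' @return Deflection cosines in `[-1, 1]`, one per element of `u`.
#' @examples
#' mean(sample_hg(0.9, runif(1e5)))  # ~0.9
#' @export
sample_hg <- function(g, u) {
  if (abs(g) >= 1) stop("g must lie strictly inside (-1, 1)")
  if (any(u < 0) || any(u >= 1)) stop("u must lie in [0, 1)")
  if (abs(g) < 1e-9) return(2 * u - 1)
  f <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - f^2) / (2 * g)))
}

#' Forward Monte Carlo photon transport through a bioink slab
#'
#' Weighted-photon (MCML-style) transport: exponential free paths with
#' `mu_t = mu_a + mu_s`, fractional absorption `mu_a / mu_t` per interaction,
#' Henyey-Greenstein scattering, stochastic unpolarized Fresnel
#' reflection/refraction at both faces (entry specular reflection included in
#' `R_total` and reported separately as `R_specular`), Snell refraction of
#' exit directions into the ambient medium, and Russian roulette below the
#' weight threshold. Tallies are deterministic given `(seed, cfg)`.
#'
#' @param props [optical_properties()] of the slab medium.
#' @param geom [slab_geometry()].
#' @param cfg [tally_config()].
#' @return An object of class `transport_result`: total transmittance /
#'   reflectance / absorbed fractions, specular reflectance, exit-angle
#'   histogram (fraction of transmitted weight per bin), batch standard
#'   errors of T and R, and — when `cfg$depth_slices` is set — a `psf_stack`.
#' @examples
#' r <- run_forward(optical_properties(mu_s = 5, g = 0.9, n = 1.34),
#'                  slab_geometry(1), tally_config(n_photons = 1e4, seed = 7))
#' r$T_total + r$R_total + r$A_total  # ~1
#' @export
run_forward <- function(props, geom = slab_geometry(), cfg = tally_config()) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(geom, "slab_geometry"), inherits(cfg, "tally_config"))
  depths_mm <- if (is.null(cfg$depth_slices)) numeric(0)
               else cfg$depth_slices / 1000
  if (length(depths_mm) && any(depths_mm >= geom$thickness))
    stop("depth_slices must lie strictly inside the slab")
  half_cells <- as.integer(round(cfg$lateral_extent / cfg$lateral_pitch))

  raw <- mc_slab_cpp(props$mu_a, props$mu_s, props$g, props$n,
                     geom$thickness, geom$n_ambient,
                     cfg$n_photons, cfg$seed, cfg$angular_bin_deg,
                     depths_mm, cfg$lateral_pitch / 1000, half_cells,
                     cfg$roulette_threshold, cfg$roulette_survival,
                     cfg$n_batches)

  nb <- length(raw$batch_T)
  se <- c(T = stats::sd(raw$batch_T) / sqrt(nb),
          R = stats::sd(raw$batch_R) / sqrt(nb))

  n_bins <- length(raw$ang_weight)
  edges <- seq(0, by = cfg$angular_bin_deg, length.out = n_bins + 1L)
  tot <- sum(raw$ang_weight)
  frac <- if (tot > 0) raw$ang_weight / tot else rep(0, n_bins)

  psf <- NULL
  if (!is.null(raw$psf)) {
    kern <- lapply(seq_along(cfg$depth_slices), function(k) {
      m <- raw$psf[, , k]
      s <- sum(m)
      if (s > 0) m / s else m
    })
    psf <- structure(list(depths = cfg$depth_slices, kernels = kern,
                          pitch = cfg$lateral_pitch,
                          lost_fraction = raw$psf_lost /
                            pmax(raw$psf_lost + vapply(
                              seq_along(kern), function(k) sum(raw$psf[, , k]),
                              numeric(1)), .Machine$double.eps)),
                     class = "psf_stack")
  }

  structure(list(T_total = raw$T_total, R_total = raw$R_total,
                 R_specular = raw$R_specular, A_total = raw$A_total,
                 angular_hist = list(edges_deg = edges, fraction = frac),
                 batch_se = se, psf_stack = psf,
                 props = props, geom = geom,
                 seed = cfg$seed, n_photons = cfg$n_photons),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf("Slab transport (%g photons, seed %d)\n", x$n_photons, x$seed))
  cat(sprintf("  T = %.5f (SE %.2g)   R = %.5f (SE %.2g, specular %.5f)\n",
              x$T_total, x$batch_se["T"], x$R_total, x$batch_se["R"],
              x$R_specular))
  cat(sprintf("  A = %.5f   T+R+A = %.5f\n", x$A_total,
              x$T_total + x$R_total + x$A_total))
  invisible(x)
}

#' Exit-angle distribution of transmitted light
#'
#' Histogram of transmitted photon weight over the exit polar angle measured
#' in the ambient medium, as a goniometer would record it.
#'
#' @param result A `transport_result` from [run_forward()].
#' @param per_solid_angle If `TRUE`, divide each bin by its solid angle
#'   (radiance-style output); fractions then no longer sum to 1.
#' @return A data frame with `angle_lo`, `angle_hi` (degrees) and `fraction`.
#'   With zero transmitted weight an empty (zero-row) data frame is returned.
#' @export
angular_distribution <- function(result, per_solid_angle = FALSE) {
  stopifnot(inherits(result, "transport_result"))
  h <- result$angular_hist
  if (result$T_total <= 0)
    return(data.frame(angle_lo = numeric(0), angle_hi = numeric(0),
                      fraction = numeric(0)))
  lo <- h$edges_deg[-length(h$edges_deg)]
  hi <- h$edges_deg[-1]
  frac <- h$fraction
  if (per_solid_angle) {
    omega <- 2 * pi * (cos(lo * pi / 180) - cos(hi * pi / 180))
    frac <- frac / omega
  }
  data.frame(angle_lo = lo, angle_hi = hi, fraction = frac)
}

#' Depth-resolved point-spread functions of a pencil beam
#'
#' Runs the forward model with a collimated pencil beam at normal incidence
#' and tallies the lateral weight distribution at each requested depth plane
#' (every downward crossing). Each kernel is normalized to unit sum; the
#' convolution of a kernel with a projected pattern predicts in-bioink
#' blurring at that depth.
#'
#' @param props [optical_properties()].
#' @param geom [slab_geometry()].
#' @param cfg [tally_config()]; `depth_slices` defaults to every 10 um down
#'   to 250 um (the thickness of the resolution test structures) when unset.
#' @return A `psf_stack`: depths (um), list of normalized kernels, grid pitch
#'   (um per cell) and the weight fraction lost outside the grid per depth.
#' @export
psf_stack <- function(props, geom = slab_geometry(), cfg = tally_config()) {
  if (is.null(cfg$depth_slices)) {
    cfg$depth_slices <- seq(10, min(250, geom$thickness * 1000 - 10), by = 10)
  }
  run_forward(props, geom, cfg)$psf_stack
}

#' Root-mean-square lateral radius of each PSF kernel
#'
#' @param psf A `psf_stack`.
#' @return Named numeric vector of RMS radii in micrometres, one per depth.
#' @export
psf_rms_radius <- function(psf) {
  stopifnot(inherits(psf, "psf_stack"))
  side <- nrow(psf$kernels[[1]])
  half <- (side - 1) / 2
  coord <- (seq_len(side) - 1 - half) * psf$pitch
  r2 <- outer(coord^2, coord^2, `+`)
  out <- vapply(psf$kernels, function(k) sqrt(sum(k * r2)), numeric(1))
  names(out) <- paste0(psf$depths, "um")
  out
}

#' @export
print.psf_stack <- function(x, ...) {
  cat(sprintf("PSF stack: %d depth planes (%g-%g um), %dx%d grid at %g um\n",
              length(x$depths), min(x$depths), max(x$depths),
              nrow(x$kernels[[1]]), ncol(x$kernels[[1]]), x$pitch))
  invisible(x)
}
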