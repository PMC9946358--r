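#' Optical properties of one bioink condition
#'
#' Bundles the absorption coefficient, scattering coefficient, scattering
#' anisotropy and refractive index of a turbid bioink at the working
#' wavelength (405 nm by convention). All coefficients are per millimetre.
#'
#' @param mu_s Scattering coefficient, mm^-1 (>= 0).
#' @param g Scattering anisotropy, the mean cosine of the single-scattering
#'   deflection angle; must lie strictly inside (-1, 1).
#' @param mu_a Absorption coefficient, mm^-1 (>= 0). Dye-free measurement
#'   bioinks are modelled as non-absorbing, hence the default 0.
#' @param n Refractive index of the bioink (>= 1).
#' @param label Optional condition label (e.g. `"IDX0"`).
#' @return An object of class `optical_properties`: a list with fields
#'   `mu_a`, `mu_s`, `g`, `n`, `label` and the derived reduced scattering
#'   coefficient `mu_s_prime = mu_s * (1 - g)`.
#' @examples
#' optical_properties(mu_s = 11.76, g = 0.98605, n = 1.34)
#' @export
optical_properties <- function(mu_s, g, mu_a = 0, n = 1.34, label = NULL) {
  stopifnot(is.numeric(mu_s), length(mu_s) == 1L, is.finite(mu_s),
            is.numeric(g), length(g) == 1L, is.finite(g),
            is.numeric(mu_a), length(mu_a) == 1L, is.finite(mu_a),
            is.numeric(n), length(n) == 1L, is.finite(n))
  if (mu_s < 0) stop("mu_s must be >= 0")
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (g <= -1 || g >= 1) stop("g must lie strictly inside (-1, 1)")
  if (n < 1) stop("n must be >= 1")
  structure(
    list(mu_a = mu_a, mu_s = mu_s, g = g, n = n,
         mu_s_prime = mu_s * (1 - g), label = label),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  lbl <- if (is.null(x$label)) "" else paste0(" [", x$label, "]")
  cat(sprintf("Optical properties%s\n", lbl))
  cat(sprintf("  mu_a = %g mm^-1, mu_s = %g mm^-1, g = %g\n",
              x$mu_a, x$mu_s, x$g))
  cat(sprintf("  mu_s' = %g mm^-1, n = %g\n", x$mu_s_prime, x$n))
  invisible(x)
}

#' Reduced scattering coefficient
#'
#' The similarity relation `mu_s' = mu_s * (1 - g)`: the isotropic-equivalent
#' scattering rate that governs diffuse light spread in a forward-peaked
#' medium.
#'
#' @param mu_s Scattering coefficient, mm^-1 (>= 0).
#' @param g Anisotropy in (-1, 1).
#' @return Reduced scattering coefficient in mm^-1.
#' @examples
#' reduced_scattering(11.76, 0.98605)  # ~0.164 mm^-1
#' @export
reduced_scattering <- function(mu_s, g) {
  if (any(mu_s < 0)) stop("mu_s must be >= 0")
  if (any(g <= -1) || any(g >= 1)) stop("g must lie strictly inside (-1, 1)")
  mu_s * (1 - g)
}

#' Anisotropy implied by a (mu_s, mu_s') pair
#'
#' Inverse of [reduced_scattering()]; used to recover the anisotropy from a
#' reported scattering / reduced-scattering coefficient pair.
#'
#' @param mu_s Scattering coefficient, mm^-1 (> 0).
#' @param mu_s_prime Reduced scattering coefficient, mm^-1, with
#'   `0 <= mu_s_prime <= mu_s`.
#' @return Anisotropy `1 - mu_s_prime / mu_s`.
#' @examples
#' anisotropy_from(11.76, 0.164)  # 0.98605...
#' @export
anisotropy_from <- function(mu_s, mu_s_prime) {
  if (any(mu_s <= 0)) stop("mu_s must be > 0")
  if (any(mu_s_prime < 0)) stop("mu_s_prime must be >= 0")
  if (any(mu_s_prime > mu_s)) stop("mu_s_prime cannot exceed mu_s")
  1 - mu_s_prime / mu_s
}

#' Unpolarized Fresnel power reflectance
#'
#' Average of the s- and p-polarized Fresnel reflectances for a ray crossing a
#' planar interface from index `n_in` to `n_out`. Beyond the critical angle
#' (possible only when `n_in > n_out`) the reflectance is exactly 1.
#'
#' @param n_in,n_out Refractive indices on the incident and far side (>= 1).
#' @param cos_theta_in Cosine of the incidence angle, in (0, 1].
#' @return Power reflectance in `[0, 1]`.
#' @examples
#' fresnel_unpolarized(1.0, 1.5, 1.0)  # 0.04 at normal incidence
#' @export
fresnel_unpolarized <- function(n_in, n_out, cos_theta_in) {
  stopifnot(all(n_in >= 1), all(n_out >= 1))
  if (any(cos_theta_in <= 0) || any(cos_theta_in > 1))
    stop("cos_theta_in must lie in (0, 1]")
  n1 <- n_in; n2 <- n_out; ci <- cos_theta_in
  sin_t <- n1 / n2 * sqrt(pmax(0, 1 - ci^2))
  tir <- sin_t >= 1
  ct <- sqrt(pmax(0, 1 - pmin(sin_t, 1)^2))
  rs <- ((n1 * ci - n2 * ct) / (n1 * ci + n2 * ct))^2
  rp <- ((n1 * ct - n2 * ci) / (n1 * ct + n2 * ci))^2
  r <- 0.5 * (rs + rp)
  r[tir] <- 1
  r[abs(n1 - n2) < 1e-12] <- 0
  r
}

#' Linear refractive-index mixing model for iodixanol-supplemented bioink
#'
#' Two anchor points (concentration in % w/v, refractive index at 405 nm)
#' define a linear concentration-to-index map. The default anchors are a
#' water-like hydrogel bioink at 0% (n = 1.333) and the commercial 60%
#' iodixanol stock (n = 1.45). Linearity has empirical support over roughly
#' 20-35% iodixanol; outside that window the map is an anchored extrapolation
#' and [mix_refractive_index()] warns.
#'
#' @param anchors 2 x 2 numeric matrix (or 2-row data frame), columns
#'   `(concentration %, index)`; concentrations distinct, indices strictly
#'   increasing with concentration.
#' @param valid_range Concentration interval within `[0, 60]` over which the
#'   model may be evaluated without the `extrapolate` flag.
#' @param linear_range Concentration window over which linearity is
#'   empirically supported; evaluations outside it trigger a warning.
#' @return An object of class `mixing_model`.
#' @export
mixing_model <- function(anchors = rbind(c(0, 1.333), c(60, 1.45)),
                         valid_range = c(0, 60),
                         linear_range = c(20, 35)) {
  anchors <- as.matrix(anchors)
  stopifnot(nrow(anchors) == 2L, ncol(anchors) == 2L, all(is.finite(anchors)))
  if (anchors[1, 1] == anchors[2, 1]) stop("anchor concentrations must differ")
  o <- order(anchors[, 1])
  anchors <- anchors[o, , drop = FALSE]
  if (diff(anchors[, 2]) <= 0)
    stop("indices must increase strictly with concentration")
  if (valid_range[1] < 0 || valid_range[2] > 60)
    stop("valid_range must lie within [0, 60]")
  structure(list(anchors = unname(anchors), valid_range = valid_range,
                 linear_range = linear_range),
            class = "mixing_model")
}

#' Refractive index of a bioink at a given iodixanol concentration
#'
#' Linear interpolation between the two anchors of a [mixing_model()].
#'
#' @param c_idx Iodixanol concentration, % w/v.
#' @param model A [mixing_model()].
#' @param extrapolate Allow evaluation outside `model$valid_range`.
#' @return Refractive index at 405 nm.
#' @examples
#' suppressWarnings(mix_refractive_index(30))  # 1.3915 with default anchors
#' @export
mix_refractive_index <- function(c_idx, model = mixing_model(),
                                 extrapolate = FALSE) {
  stopifnot(inherits(model, "mixing_model"), is.numeric(c_idx))
  vr <- model$valid_range
  if (!extrapolate && (any(c_idx < vr[1]) || any(c_idx > vr[2])))
    stop(sprintf("concentration outside valid range [%g, %g]%%; set extrapolate = TRUE to override",
                 vr[1], vr[2]))
  lr <- model$linear_range
  if (any(c_idx < lr[1] - 1e-9 | c_idx > lr[2] + 1e-9))
    warning(sprintf(
      "linearity of the index-concentration map is only supported over %g-%g%% iodixanol",
      lr[1], lr[2]))
  a <- model$anchors
  slope <- (a[2, 2] - a[1, 2]) / (a[2, 1] - a[1, 1])
  a[1, 2] + slope * (c_idx - a[1, 1])
}

#' Iodixanol concentration required to reach a target refractive index
#'
#' Inverse of [mix_refractive_index()] on the anchor-bounded index interval,
#' e.g. to match the bioink to a cytoplasm index of 1.36-1.39.
#'
#' @param n_target Target refractive index; must lie within the anchors'
#'   index range.
#' @param model A [mixing_model()].
#' @return Concentration in % w/v. A `note` attribute flags results outside
#'   the empirically supported 20-35% window.
#' @examples
#' suppressWarnings(required_idx_for_target(1.39))  # ~29.2%
#' @export
required_idx_for_target <- function(n_target, model = mixing_model()) {
  stopifnot(inherits(model, "mixing_model"), is.numeric(n_target))
  a <- model$anchors
  if (any(n_target < a[1, 2]) || any(n_target > a[2, 2]))
    stop(sprintf("n_target outside anchor index range [%g, %g]",
                 a[1, 2], a[2, 2]))
  slope <- (a[2, 2] - a[1, 2]) / (a[2, 1] - a[1, 1])
  conc <- a[1, 1] + (n_target - a[1, 2]) / slope
  lr <- model$linear_range
  out_of_window <- conc < lr[1] - 1e-9 | conc > lr[2] + 1e-9
  if (any(out_of_window)) {
    warning(sprintf(
      "required concentration outside the empirically linear %g-%g%% window",
      lr[1], lr[2]))
    attr(conc, "note") <- "outside empirically linear window"
  }
  conc
}
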