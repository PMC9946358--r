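#' Construct a slab measurement record
#'
#' One slab's observables as the inverse stage consumes them: total
#' transmittance, total reflectance, a binned angular scan of the transmitted
#' light, and the geometry metadata needed to run the forward model.
#'
#' @param T_total,R_total Total transmittance and reflectance fractions;
#'   nonnegative with `T_total + R_total <= 1`.
#' @param angular List with `edges_deg` (n+1 increasing bin edges, degrees)
#'   and `fraction` (n per-bin fractions summing to 1 within 1e-6).
#' @param thickness Slab thickness, mm.
#' @param n_sample,n_ambient Refractive indices of the sample and the
#'   surrounding medium.
#' @param wavelength Wavelength, nm.
#' @param noise_sd Optional named relative SDs of the observables.
#' @param meta Optional metadata list (generating truth, seeds, provenance).
#' @return An object of class `measurement`.
#' @export
measurement <- function(T_total, R_total, angular, thickness = 1,
                        n_sample = 1.34, n_ambient = 1, wavelength = 405,
                        noise_sd = NULL, meta = list()) {
  m <- structure(list(T_total = T_total, R_total = R_total, angular = angular,
                      thickness = thickness, n_sample = n_sample,
                      n_ambient = n_ambient, wavelength = wavelength,
                      noise_sd = noise_sd, meta = meta),
                 class = "measurement")
  validate_measurement(m)
  m
}

#' Validate a measurement record's invariants
#'
#' @param m A `measurement`.
#' @return `m`, invisibly; stops with the offending field named otherwise.
#' @export
validate_measurement <- function(m) {
  fail <- function(field, why) stop(sprintf("measurement field '%s': %s",
                                            field, why), call. = FALSE)
  for (f in c("T_total", "R_total", "thickness", "n_sample", "n_ambient"))
    if (!is.numeric(m[[f]]) || length(m[[f]]) != 1L || !is.finite(m[[f]]))
      fail(f, "must be a finite scalar")
  if (m$T_total < 0 || m$T_total > 1) fail("T_total", "must lie in [0, 1]")
  if (m$R_total < 0 || m$R_total > 1) fail("R_total", "must lie in [0, 1]")
  if (m$T_total + m$R_total > 1 + 1e-9)
    fail("T_total", "T_total + R_total must not exceed 1")
  if (m$thickness <= 0) fail("thickness", "must be > 0")
  if (m$n_sample < 1) fail("n_sample", "must be >= 1")
  if (m$n_ambient < 1) fail("n_ambient", "must be >= 1")
  a <- m$angular
  if (!is.list(a) || is.null(a$edges_deg) || is.null(a$fraction))
    fail("angular", "must contain edges_deg and fraction")
  if (length(a$edges_deg) != length(a$fraction) + 1L)
    fail("angular", "edges_deg must have one more element than fraction")
  if (any(diff(a$edges_deg) <= 0)) fail("angular", "edges must increase")
  if (any(a$fraction < 0)) fail("angular", "fractions must be nonnegative")
  if (length(a$fraction) &&
      abs(sum(a$fraction) - 1) > 1e-6 && sum(a$fraction) != 0)
    fail("angular", "fractions must sum to 1 within 1e-6")
  invisible(m)
}

#' @export
print.measurement <- function(x, ...) {
  cat(sprintf("Measurement: T = %.5f, R = %.5f, %d angular bins\n",
              x$T_total, x$R_total, length(x$angular$fraction)))
  cat(sprintf("  slab %g mm, n_sample %g, n_ambient %g, %g nm\n",
              x$thickness, x$n_sample, x$n_ambient, x$wavelength))
  if (!is.null(x$meta$truth))
    cat(sprintf("  synthetic truth: mu_s = %g, g = %g, mu_a = %g\n",
                x$meta$truth$mu_s, x$meta$truth$g, x$meta$truth$mu_a))
  invisible(x)
}
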