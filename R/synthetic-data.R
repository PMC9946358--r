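#' Measurement noise model
#'
#' Instrument noise applied to forward-model tallies when generating
#' synthetic measurements. The default is 1% multiplicative Gaussian noise on
#' the scalars and 2% per angular bin — an instrument-grade convention, since
#' replicate-to-replicate variances of real integrating-sphere/goniometer
#' setups vary. A Poisson-counts mode emulates shot-noise-limited angular
#' scans.
#'
#' @param rel_sd_T,rel_sd_R Relative SD of total transmittance / reflectance.
#' @param rel_sd_angular Relative SD per angular bin (gaussian mode).
#' @param mode `"gaussian-multiplicative"` or `"poisson-counts"`.
#' @param counts_scale Expected counts in the peak angular bin (poisson mode).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(rel_sd_T = 0.01, rel_sd_R = 0.01,
                        rel_sd_angular = 0.02,
                        mode = c("gaussian-multiplicative", "poisson-counts"),
                        counts_scale = 1e5) {
  mode <- match.arg(mode)
  stopifnot(rel_sd_T >= 0, rel_sd_R >= 0, rel_sd_angular >= 0)
  if (mode == "poisson-counts") stopifnot(counts_scale >= 1)
  structure(list(rel_sd_T = rel_sd_T, rel_sd_R = rel_sd_R,
                 rel_sd_angular = rel_sd_angular, mode = mode,
                 counts_scale = counts_scale),
            class = "noise_model")
}

#' Noise-free noise model
#' @return A [noise_model()] with all SDs zero.
#' @export
noise_free <- function() noise_model(0, 0, 0)

#' Bundled optical-property presets for the two headline bioink conditions
#'
#' `"IDX0"`: 5% GelMA bioink with 40 million cells/ml and no iodixanol
#' (mu_s = 11.76 mm^-1, mu_s' = 0.164 mm^-1, hence g = 1 - 0.164/11.76 =
#' 0.98605...; n = 1.34, water-like with solutes). `"IDX30"`: the same bioink
#' refractive-index matched with 30% iodixanol (mu_s = 1.377 mm^-1, mu_s' =
#' 0.014 mm^-1, hence g = 0.98983...; n = 1.39, matched toward cytoplasm).
#' The anisotropies are derived from the (mu_s, mu_s') pairs because g is
#' reported only graphically; the sample indices are stated assumptions and
#' can be overridden.
#'
#' @param label `"IDX0"` or `"IDX30"`.
#' @param n Override the assumed sample refractive index.
#' @return An [optical_properties()] object with a `provenance` attribute.
#' @export
condition_preset <- function(label = c("IDX0", "IDX30"), n = NULL) {
  label <- match.arg(label)
  p <- switch(label,
    IDX0 = list(mu_s = 11.76, mu_s_prime = 0.164, n = 1.34),
    IDX30 = list(mu_s = 1.377, mu_s_prime = 0.014, n = 1.39))
  if (!is.null(n)) p$n <- n
  props <- optical_properties(mu_s = p$mu_s,
                              g = anisotropy_from(p$mu_s, p$mu_s_prime),
                              mu_a = 0, n = p$n, label = label)
  attr(props, "provenance") <- paste(
    "g derived from the reported (mu_s, mu_s') pair;",
    "sample index is an assumption (water-like bioink / cytoplasm-matched).")
  props
}

# Apply a noise model to (T, R, angular fractions); renormalizes the scan.
apply_measurement_noise <- function(T_total, R_total, frac, noise, seed) {
  withr::with_seed(seed, {
    if (noise$mode == "gaussian-multiplicative") {
      T_total <- T_total * (1 + noise$rel_sd_T * stats::rnorm(1))
      R_total <- R_total * (1 + noise$rel_sd_R * stats::rnorm(1))
      if (noise$rel_sd_angular > 0 && length(frac)) {
        frac <- frac * (1 + noise$rel_sd_angular * stats::rnorm(length(frac)))
      }
    } else {
      peak <- max(frac)
      if (peak > 0) {
        lam <- frac / peak * noise$counts_scale
        frac <- stats::rpois(length(lam), lam)
      }
      T_total <- T_total * (1 + noise$rel_sd_T * stats::rnorm(1))
      R_total <- R_total * (1 + noise$rel_sd_R * stats::rnorm(1))
    }
    frac <- pmax(frac, 0)
    if (sum(frac) > 0) frac <- frac / sum(frac)
    list(T_total = min(max(T_total, 0), 1),
         R_total = min(max(R_total, 0), 1), frac = frac)
  })
}

#' Generate a synthetic slab measurement
#'
#' Runs the forward Monte Carlo model and applies the noise model
#' independently per observable (the angular scan is renormalized after
#' noising). The generating truth, seeds and noise model are stamped into the
#' record's metadata, making every fixture self-describing for automated
#' parameter-recovery scoring.
#'
#' @param props Generating [optical_properties()] (the truth).
#' @param geom [slab_geometry()].
#' @param noise [noise_model()]; use [noise_free()] for exact tallies.
#' @param seed Integer seed (drives both the forward run and the noise draw).
#' @param cfg [tally_config()] for the forward run; its seed is overridden
#'   by `seed`.
#' @return A [measurement()].
#' @export
synth_measurement <- function(props, geom = slab_geometry(),
                              noise = noise_model(), seed = 1,
                              cfg = tally_config()) {
  cfg$seed <- as.integer(seed)
  sim <- run_forward(props, geom, cfg)
  noised <- apply_measurement_noise(sim$T_total, sim$R_total,
                                    sim$angular_hist$fraction, noise,
                                    seed + 271L)
  measurement(
    T_total = noised$T_total, R_total = noised$R_total,
    angular = list(edges_deg = sim$angular_hist$edges_deg,
                   fraction = noised$frac),
    thickness = geom$thickness, n_sample = props$n,
    n_ambient = geom$n_ambient, wavelength = geom$wavelength,
    noise_sd = c(T = noise$rel_sd_T, R = noise$rel_sd_R,
                 angular = noise$rel_sd_angular),
    meta = list(truth = list(mu_s = props$mu_s, g = props$g,
                             mu_a = props$mu_a, n = props$n,
                             mu_s_prime = props$mu_s_prime,
                             label = props$label),
                seed = seed, n_photons = cfg$n_photons,
                noise_mode = noise$mode, synthetic = TRUE))
}

#' Generate a synthetic refractometer boundary reading
#'
#' Inverse of the calibration mapping plus Gaussian pixel noise: the pixel
#' position at which the total-internal-reflection boundary of a sample of
#' index `n_sample` would appear on the camera.
#'
#' @param n_sample Sample refractive index, below the prism index.
#' @param cal A [refractometer_calibration()].
#' @param noise_sd_px SD of the Gaussian pixel noise.
#' @param seed Integer seed.
#' @return Boundary position in pixels.
#' @export
synth_refractometer_reading <- function(n_sample, cal, noise_sd_px = 0,
                                        seed = 1) {
  stopifnot(inherits(cal, "refractometer_calibration"))
  if (n_sample >= cal$n_prism)
    stop("n_sample must be below the prism index (no TIR otherwise)")
  theta <- critical_angle_deg(n_sample, cal$n_prism)
  px <- (theta - cal$map["intercept"]) / cal$map["slope"]
  withr::with_seed(seed, unname(px + noise_sd_px * stats::rnorm(1)))
}

#' Write a complete synthetic fixture bundle
#'
#' Writes, under `out_dir`: noise-free and 1%-noise measurements for the
#' IDX0 and IDX30 presets, a line-pair ladder and a 12-spoke projection
#' pattern, a refractometer calibration with a set of readings, and a
#' manifest JSON listing every file with its generating truth and seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; sub-seeds are derived deterministically.
#' @param n_photons Photons for the forward runs behind the measurements.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
make_fixture_bundle <- function(out_dir, seed = 1, n_photons = 2e5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, files = list())
  add <- function(path, what, truth = NULL) {
    manifest$files[[length(manifest$files) + 1L]] <<-
      list(path = basename(path), what = what, truth = truth)
  }

  geom <- slab_geometry(1)
  cfg <- tally_config(n_photons = n_photons)
  k <- 0L
  for (lbl in c("IDX0", "IDX30")) {
    props <- condition_preset(lbl)
    truth <- list(mu_s = props$mu_s, g = props$g, mu_a = props$mu_a,
                  n = props$n, mu_s_prime = props$mu_s_prime)
    for (nz in c("clean", "noisy")) {
      k <- k + 1L
      noise <- if (nz == "clean") noise_free()
               else noise_model(0.01, 0.01, 0.01)
      m <- synth_measurement(props, geom, noise, seed = seed + k, cfg = cfg)
      path <- file.path(out_dir, sprintf("measurement_%s_%s.json", lbl, nz))
      save_measurement(m, path)
      add(path, sprintf("%s measurement (%s)", lbl, nz), truth)
    }
  }

  spoke <- make_spoke_pattern(n_spokes = 12, diameter = 2000, pitch = 5)
  p1 <- file.path(out_dir, "pattern_spoke12.png")
  save_pattern(spoke, p1)
  add(p1, "12-spoke binary test pattern, 2 mm diameter, 5 um pitch")

  ladder <- make_line_pairs(periods = c(40, 80, 160, 320), pitch = 5)
  p2 <- file.path(out_dir, "pattern_linepairs.png")
  save_pattern(ladder, p2)
  add(p2, "line-pair ladder, periods 40-320 um")

  cal <- refractometer_calibration(
    standards = data.frame(pixel = c(200, 800), n = c(1.3330, 1.3776)),
    n_prism = 1.8421)
  p3 <- file.path(out_dir, "refractometer_calibration.json")
  jsonlite::write_json(list(schema = "inkoptics/calibration/1",
                            n_prism = cal$n_prism,
                            standards = cal$standards,
                            map = as.list(cal$map)),
                       p3, auto_unbox = TRUE, digits = NA)
  add(p3, "two-standard refractometer calibration (synthetic pixel map)")

  targets <- c(1.3330, 1.3600, 1.3915, 1.4500)
  readings <- vapply(seq_along(targets), function(i)
    synth_refractometer_reading(targets[i], cal, noise_sd_px = 0.5,
                                seed = seed + 100L + i), numeric(1))
  p4 <- file.path(out_dir, "refractometer_readings.json")
  jsonlite::write_json(list(schema = "inkoptics/readings/1",
                            truth_n = targets, pixel = readings,
                            noise_sd_px = 0.5, seed = seed),
                       p4, auto_unbox = TRUE, digits = NA)
  add(p4, "synthetic TIR boundary readings", list(n = targets))

  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
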