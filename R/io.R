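SCHEMA_MEASUREMENT <- "inkoptics/measurement/1"
SCHEMA_PATTERN <- "inkoptics/pattern/1"
SCHEMA_PSF <- "inkoptics/psf/1"
SCHEMA_FIT <- "inkoptics/fit/1"

#' Save a measurement record
#'
#' JSON (`.json`) stores the full record including metadata. CSV (`.csv`)
#' stores the angular table (`angle_deg_lo`, `angle_deg_hi`, `fraction`)
#' preceded by a commented header block with the scalars and geometry.
#'
#' @param m A [measurement()].
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
save_measurement <- function(m, path) {
  validate_measurement(m)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(schema = SCHEMA_MEASUREMENT, T_total = m$T_total,
           R_total = m$R_total,
           angular = list(edges_deg = m$angular$edges_deg,
                          fraction = m$angular$fraction),
           thickness = m$thickness, n_sample = m$n_sample,
           n_ambient = m$n_ambient, wavelength = m$wavelength,
           noise_sd = as.list(m$noise_sd), meta = m$meta),
      path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    hdr <- c(sprintf("# schema: %s", SCHEMA_MEASUREMENT),
             sprintf("# T_total: %.17g", m$T_total),
             sprintf("# R_total: %.17g", m$R_total),
             sprintf("# thickness: %.17g", m$thickness),
             sprintf("# n_sample: %.17g", m$n_sample),
             sprintf("# n_ambient: %.17g", m$n_ambient),
             sprintf("# wavelength: %.17g", m$wavelength))
    tab <- data.frame(
      angle_deg_lo = m$angular$edges_deg[-length(m$angular$edges_deg)],
      angle_deg_hi = m$angular$edges_deg[-1],
      fraction = m$angular$fraction)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(format(tab, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, quote = FALSE)
  } else stop("unsupported measurement format: ", ext)
  invisible(path)
}

#' Load and validate a measurement record
#'
#' @param path A `.json` or `.csv` file written by [save_measurement()].
#' @return A validated [measurement()].
#' @export
load_measurement <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(j$schema) || !startsWith(j$schema, "inkoptics/measurement"))
      stop("unrecognized measurement schema in ", path)
    measurement(T_total = j$T_total, R_total = j$R_total,
                angular = list(edges_deg = j$angular$edges_deg,
                               fraction = j$angular$fraction),
                thickness = j$thickness, n_sample = j$n_sample,
                n_ambient = j$n_ambient, wavelength = j$wavelength,
                noise_sd = unlist(j$noise_sd), meta = j$meta)
  } else if (ext == "csv") {
    lines <- readLines(path)
    hdr_lines <- grep("^#", lines, value = TRUE)
    kv <- list()
    for (h in hdr_lines) {
      mres <- regmatches(h, regexec("^# *([A-Za-z_]+): *(.+)$", h))[[1]]
      if (length(mres) == 3) kv[[mres[2]]] <- mres[3]
    }
    need <- c("T_total", "R_total", "thickness", "n_sample", "n_ambient")
    missing <- setdiff(need, names(kv))
    if (length(missing))
      stop("measurement CSV missing header field(s): ",
           paste(missing, collapse = ", "))
    tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
    measurement(T_total = as.numeric(kv$T_total),
                R_total = as.numeric(kv$R_total),
                angular = list(edges_deg = c(tab$angle_deg_lo,
                                             tab$angle_deg_hi[nrow(tab)]),
                               fraction = tab$fraction),
                thickness = as.numeric(kv$thickness),
                n_sample = as.numeric(kv$n_sample),
                n_ambient = as.numeric(kv$n_ambient),
                wavelength = if (is.null(kv$wavelength)) 405
                             else as.numeric(kv$wavelength))
  } else stop("unsupported measurement format: ", ext)
}

#' Save a pattern image with its JSON sidecar
#'
#' `.png` writes 8-bit grayscale; `.tif`/`.tiff` writes 32-bit float. The
#' sidecar (`<path>.json`) carries pitch and normalization; physical scale is
#' never implied by pixel size alone.
#'
#' @param pattern A [pattern_image()]; values must lie in `[0, 1]` for PNG.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "pattern_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (max(pattern$grid) > 1)
      stop("PNG output requires intensities in [0, 1]")
    png::writePNG(pattern$grid, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pattern$grid / max(1, max(pattern$grid)), path,
                    bits.per.sample = 32L)
  } else stop("unsupported pattern format: ", ext)
  jsonlite::write_json(list(schema = SCHEMA_PATTERN, pitch = pattern$pitch,
                            normalization = pattern$normalization),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a pattern image and its sidecar
#'
#' @param path A `.png` or `.tif`/`.tiff` written by [save_pattern()] (or any
#'   grayscale image with a conforming sidecar). Intensities are scaled to
#'   `[0, 1]` by bit depth.
#' @return A [pattern_image()].
#' @export
load_pattern <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing sidecar ", side, " (pitch is required)")
  sc <- jsonlite::read_json(side, simplifyVector = TRUE)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
         else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else stop("unsupported pattern format: ", ext)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1)
      stop("RGB input; convert the pattern to single-channel grayscale")
    img <- img[, , 1]
  }
  pattern_image(img, sc$pitch,
                if (identical(sc$normalization, "binary") &&
                    all(img %in% c(0, 1))) "binary" else "relative")
}

#' Save a PSF stack as a multi-page 32-bit float TIFF plus JSON sidecar
#'
#' @param psf A `psf_stack`.
#' @param path Output `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
save_psf_stack <- function(psf, path) {
  stopifnot(inherits(psf, "psf_stack"))
  tiff::writeTIFF(psf$kernels, path, bits.per.sample = 32L)
  jsonlite::write_json(list(schema = SCHEMA_PSF, depths = psf$depths,
                            pitch = psf$pitch, normalization = "unit-sum"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a PSF stack written by [save_psf_stack()]
#'
#' @param path The `.tif`/`.tiff` path.
#' @return A `psf_stack`.
#' @export
load_psf_stack <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar ", side)
  sc <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  structure(list(depths = sc$depths, kernels = pages, pitch = sc$pitch),
            class = "psf_stack")
}

#' Save a fit result as JSON
#'
#' @param fit A `fit_result` from [fit_optical_properties()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  cfg <- fit$config
  jsonlite::write_json(
    list(schema = SCHEMA_FIT, mu_s_hat = fit$mu_s_hat, g_hat = fit$g_hat,
         mu_a_hat = fit$mu_a_hat, mu_s_prime_hat = fit$mu_s_prime_hat,
         objective = fit$objective, trace = fit$trace, seed = fit$seed,
         config = list(n_particles = cfg$n_particles,
                       n_iterations = cfg$n_iterations,
                       photons_per_eval = cfg$photons_per_eval,
                       inertia = cfg$inertia, cognitive = cfg$cognitive,
                       social = cfg$social, weights = as.list(cfg$weights),
                       fit_mu_a = cfg$fit_mu_a, bounds = cfg$bounds)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
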