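#' Write / read a portal image
#'
#' The lossless primary format is 16-bit single-channel TIFF with a JSON
#' metadata sidecar (`<path>.json` recording beam mode, pixel spacing, seed
#' and degradation parameters). An optional 8-bit PNG preview can be written
#' alongside for quick viewing; the preview is not meant for analysis.
#'
#' @param img A [portal_image()] (quantised pixel values).
#' @param path Output path ending in `.tif`/`.tiff`.
#' @param preview_png Optional path for an 8-bit preview PNG.
#' @return `write_portal_image` returns `path` invisibly; `read_portal_image`
#'   the [portal_image()] with metadata restored from the sidecar.
#' @export
write_portal_image <- function(img, path, preview_png = NULL) {
  stopifnot(inherits(img, "portal_image"))
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop("unknown extension: portal images are written as .tif/.tiff",
         call. = FALSE)
  }
  px <- round(img$pixels)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16,
                  compression = "deflate")
  side <- list(
    beam_mode = img$beam_mode,
    pixel_spacing_mm = img$pixel_spacing,
    inverted = img$inverted,
    seed = img$meta$seed,
    psf_sigma_mm = img$meta$psf_sigma_mm,
    noise = as.list(img$meta$noise),
    gain = img$meta$gain,
    magnification = img$meta$magnification,
    ideal_levels = img$meta$ideal_levels
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(preview_png)) {
    png::writePNG(px / 65535, preview_png)
  }
  invisible(path)
}

#' @rdname write_portal_image
#' @export
read_portal_image <- function(path) {
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop("unknown extension: expected a .tif/.tiff portal image", call. = FALSE)
  }
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (!is.matrix(px)) {
    stop("portal images must be single-channel", call. = FALSE)
  }
  storage.mode(px) <- "double"
  sidecar <- paste0(path, ".json")
  meta <- list()
  spacing <- NA_real_
  mode <- NA_character_
  inverted <- FALSE
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    spacing <- side$pixel_spacing_mm %||% NA_real_
    mode <- side$beam_mode %||% NA_character_
    inverted <- isTRUE(side$inverted)
    meta <- side[setdiff(names(side),
                         c("pixel_spacing_mm", "beam_mode", "inverted"))]
    if (!is.null(meta$ideal_levels)) {
      meta$ideal_levels <- lapply(meta$ideal_levels, unlist)
    }
  }
  if (is.na(spacing)) {
    stop("missing pixel spacing: no metadata sidecar found for ", path,
         call. = FALSE)
  }
  portal_image(px, spacing, mode, inverted = inverted, meta = meta)
}

#' Write / read a 1-D dose profile as CSV
#'
#' Two-column CSV `position_mm,dose` with a header row. Reading validates
#' the format and the profile invariants; a malformed file produces an error
#' naming the offending column or line.
#'
#' @param p A [dose_profile()].
#' @param path File path.
#' @param kind,normalization Passed to [dose_profile()] on read.
#' @return `write_profile` returns `path` invisibly; `read_profile` the
#'   [dose_profile()].
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "dose_profile"))
  utils::write.csv(data.frame(position_mm = p$positions, dose = p$dose),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, kind = "pdd", normalization = "none") {
  df <- utils::read.csv(path)
  need <- c("position_mm", "dose")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("profile CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$position_mm)) || any(!is.finite(df$dose))) {
    bad <- which(!is.finite(df$position_mm) | !is.finite(df$dose))[1]
    stop("profile CSV ", path, ": non-numeric value at data line ", bad,
         call. = FALSE)
  }
  if (any(diff(df$position_mm) <= 0)) {
    bad <- which(diff(df$position_mm) <= 0)[1] + 1L
    stop("profile CSV ", path, ": positions not strictly increasing at data line ",
         bad, call. = FALSE)
  }
  dose_profile(df$position_mm, df$dose, kind = kind,
               normalization = normalization)
}

#' Read and validate a run configuration
#'
#' YAML configuration for the analysis pipeline. Required keys are
#' `beam.mode` (or `beam.modes` for a comparison run); everything else has
#' package defaults, see [default_run_config()]. An error names the first
#' missing or invalid key.
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$beam) || (is.null(cfg$beam$mode) && is.null(cfg$beam$modes))) {
    stop("config is missing required key `beam.mode`", call. = FALSE)
  }
  user_modes <- cfg$beam$modes %||% cfg$beam$mode
  cfg <- utils::modifyList(default_run_config(), cfg)
  cfg$beam$modes <- user_modes
  bad <- setdiff(cfg$beam$modes, c("al_target", "6mv"))
  if (length(bad)) {
    stop("config key `beam.mode` has unknown value: ", bad[1], call. = FALSE)
  }
  for (key in c("mtf_levels", "contrast_thresholds")) {
    v <- unlist(cfg$analysis[[key]])
    if (any(v <= 0) || any(v >= 1)) {
      stop("config key `analysis.", key, "` must lie in (0, 1)", call. = FALSE)
    }
  }
  cfg
}

#' Default pipeline configuration
#'
#' The configuration run_comparison() uses when none is supplied: both beam
#' modes, the default phantom, geometry and detectors, MTF levels 0.5/0.1,
#' contrast thresholds 5%/3%, gamma criteria 3%/3 mm at 1 mm resampling, and
#' a reduced canvas scale suitable for interactive work.
#'
#' @param scale Canvas scale factor.
#' @param seed RNG seed shared by both beam arms.
#' @return Config list.
#' @export
default_run_config <- function(scale = 0.5, seed = 1L) {
  list(
    beam = list(modes = c("al_target", "6mv"), max_energy_kev = 6000),
    filter = list(material = "polystyrene", thickness_mm = 20,
                  csda_range_mm = 20),
    detector = list(scale = scale),
    geometry = list(ssd_cm = 95.2, sid_cm = 110, field_cm = c(26, 26)),
    phantom = list(variant = "minimal"),
    analysis = list(
      mtf_levels = c(0.5, 0.1),
      contrast_thresholds = c(green = 0.05, yellow = 0.03),
      gamma = c(dose_tolerance = 3, dta = 3, resample_spacing = 1)
    ),
    dose_validation = list(
      enabled = TRUE,
      pdd_perturbation = c(1.6, 0, 0),
      profile_perturbation = c(1.0, 1.0, 0.3)
    ),
    seed = seed
  )
}
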