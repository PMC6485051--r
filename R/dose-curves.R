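#' 1-D dose profile
#'
#' Position/dose samples for a percentage-depth-dose curve (`kind = "pdd"`,
#' positions are depths from the surface) or a lateral profile
#' (`kind = "lateral"`, positions are off-axis distances). `normalization`
#' records how the dose axis is scaled: `"none"` (raw), `"max"` (percent of
#' maximum, max = 100) or `"cax"` (percent of the central-axis value,
#' 100 at position 0).
#'
#' @param positions Strictly increasing positions in mm.
#' @param dose Non-negative dose values, same length.
#' @param kind `"pdd"` or `"lateral"`.
#' @param normalization `"none"`, `"max"` or `"cax"`.
#' @param meta Optional metadata list.
#' @return A `dose_profile` object.
#' @export
dose_profile <- function(positions, dose, kind = c("pdd", "lateral"),
                         normalization = c("none", "max", "cax"),
                         meta = list()) {
  kind <- match.arg(kind)
  normalization <- match.arg(normalization)
  positions <- as.numeric(positions)
  dose <- as.numeric(dose)
  if (length(positions) != length(dose)) {
    stop("`positions` and `dose` must have equal length", call. = FALSE)
  }
  if (any(diff(positions) <= 0)) {
    stop("`positions` must be strictly increasing", call. = FALSE)
  }
  if (any(dose < 0)) stop("`dose` must be non-negative", call. = FALSE)
  structure(
    list(positions = positions, dose = dose, kind = kind,
         normalization = normalization, meta = meta),
    class = "dose_profile"
  )
}

#' @export
print.dose_profile <- function(x, ...) {
  cat(sprintf(
    "<dose_profile> %s, %d points over [%g, %g] mm, normalization=%s\n",
    x$kind, length(x$positions), min(x$positions), max(x$positions),
    x$normalization
  ))
  invisible(x)
}

# Reference curve shapes. The depth-dose is a classic build-up / exponential
# falloff product with d_max near 15 mm (the depth at which the
# aluminium-target lateral profile is taken); the lateral profile is a flat
# top with sigmoid penumbrae for a 200 mm field.
pdd_shape <- function(z, buildup_mm = 4, falloff_mm = 120) {
  (1 - exp(-z / buildup_mm)) * exp(-z / falloff_mm)
}
lateral_shape <- function(x, field_mm = 200, penumbra_mm = 3) {
  1 / (1 + exp((abs(x) - field_mm / 2) / penumbra_mm))
}

#' Generate a paired reference/evaluated dose-curve fixture
#'
#' Builds a smooth reference curve (depth dose or lateral profile) and an
#' evaluated copy transformed by a controlled perturbation: a multiplicative
#' dose offset (percent), a rigid spatial shift (mm) and additive Gaussian
#' noise (dose units). These pairs emulate the measured-vs-modelled curve
#' comparisons used to validate a beam model; the perturbation is recorded in
#' both profiles' metadata.
#'
#' @param kind `"pdd"` or `"lateral"`.
#' @param perturbation Numeric vector `c(dose_offset_percent,
#'   spatial_shift_mm, noise_sigma)` applied to the evaluated curve.
#' @param seed RNG seed for the noise component.
#' @param spacing Sample spacing of both curves (mm).
#' @param range Position range in mm; defaults to `c(0, 300)` for a depth
#'   dose and `c(-150, 150)` for a lateral profile.
#' @return List with elements `reference` and `evaluated`, both
#'   [dose_profile()]s normalized to their maximum (max = 100).
#' @export
#' @examples
#' pair <- make_dose_curve_pair("pdd", c(1.6, 0, 0))
#' max(abs(pair$evaluated$dose - pair$reference$dose))
make_dose_curve_pair <- function(kind = c("pdd", "lateral"),
                                 perturbation = c(0, 0, 0), seed = 1L,
                                 spacing = 2, range = NULL) {
  kind <- match.arg(kind)
  if (length(perturbation) != 3) {
    stop("`perturbation` must be c(dose_offset_percent, spatial_shift_mm, noise_sigma)",
         call. = FALSE)
  }
  if (is.null(range)) range <- if (kind == "pdd") c(0, 300) else c(-150, 150)
  pos <- seq(range[1], range[2], by = spacing)
  shape <- if (kind == "pdd") pdd_shape else lateral_shape
  ref_dose <- shape(pos)
  ref_dose <- 100 * ref_dose / max(ref_dose)
  ev_dose <- ref_dose * (1 + perturbation[1] / 100)
  if (perturbation[3] > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    ev_dose <- pmax(0, ev_dose + stats::rnorm(length(ev_dose), 0, perturbation[3]))
  }
  meta <- list(perturbation = c(dose_offset_percent = perturbation[1],
                                spatial_shift_mm = perturbation[2],
                                noise_sigma = perturbation[3]),
               seed = seed)
  list(
    reference = dose_profile(pos, ref_dose, kind, "max",
                             meta = c(meta, role = "reference")),
    evaluated = dose_profile(pos + perturbation[2], ev_dose, kind, "max",
                             meta = c(meta, role = "evaluated"))
  )
}
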