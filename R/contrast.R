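#' Contrast difference between a measurement and background area
#'
#' \eqn{|E - E_0| / E_0}, where `E` and `E0` are the mean detector signals
#' (proxies for the relative energy absorbed) in the measurement and
#' background areas.
#'
#' @param E Measurement-area signal (>= 0), vectorised.
#' @param E0 Background-area signal (> 0).
#' @return Contrast difference(s), a non-negative fraction.
#' @export
#' @examples
#' contrast_difference(95, 100)
contrast_difference <- function(E, E0) {
  if (any(E0 <= 0)) stop("`E0` must be positive", call. = FALSE)
  if (any(E < 0)) stop("`E` must be non-negative", call. = FALSE)
  abs(E - E0) / E0
}

#' Predicted contrast of an attenuation step
#'
#' The exponential contrast-difference law \eqn{1 - e^{-\Delta\mu t}} for a
#' measurement region whose attenuation exceeds its background by
#' \eqn{\Delta\mu} over thickness `t`.
#'
#' @param delta_mu Attenuation-coefficient difference (1/mm).
#' @param t Thickness of the measurement region (mm, >= 0).
#' @return Predicted contrast fraction.
#' @export
#' @examples
#' predicted_contrast(log(2) / 2, 2)  # half-value thickness -> 0.5
predicted_contrast <- function(delta_mu, t) {
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  1 - exp(-delta_mu * t)
}

#' Effective attenuation step of a contrast hole
#'
#' The spectrum-weighted contrast a hole of the given depth presents against
#' the element background, and the corresponding effective attenuation
#' difference. Because the beam is polychromatic the transmission ratio is
#' not a single exponential; the effective \eqn{\Delta\mu} is defined as the
#' value for which the exponential law reproduces the spectral prediction at
#' that depth, \eqn{\Delta\mu_{eff} = -\log(T(t_{el}+d)/T(t_{el})) / d}.
#'
#' @param phantom A `phantom_spec`.
#' @param beam A [beam_spectrum()].
#' @param depth Hole depth(s) in mm (> 0).
#' @return Data frame with `depth`, `contrast` (predicted fraction) and
#'   `delta_mu_eff` (1/mm).
#' @export
effective_delta_mu <- function(phantom, beam, depth) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(beam, "beam_spectrum"))
  if (any(depth <= 0)) stop("`depth` must be positive", call. = FALSE)
  mids <- spectrum_bin_mids(beam)
  w <- beam$weights / sum(beam$weights)
  base_path <- attenuation_coefficient(phantom$base_material, mids) *
    phantom$base_thickness +
    attenuation_coefficient(phantom$element_material, mids) *
    phantom$element_thickness
  mu_el <- attenuation_coefficient(phantom$element_material, mids)
  T0 <- sum(w * exp(-base_path))
  ratio <- vapply(depth, function(d) sum(w * exp(-base_path - mu_el * d)) / T0, 0)
  data.frame(depth = depth, contrast = 1 - ratio,
             delta_mu_eff = -log(ratio) / depth)
}

#' Three-band visibility classification
#'
#' Classifies a contrast difference into the visibility bands used for
#' contrast-detail scoring: `green` (distinguishable) at or above the upper
#' threshold, `yellow` (barely distinguishable) between the thresholds, and
#' `red` (indistinguishable) below the lower one. Defaults are the
#' conventional 5% and 3% cutoffs; both boundaries are inclusive from above
#' (a value of exactly 0.05 is green, exactly 0.03 is yellow).
#'
#' @param value Contrast difference(s), >= 0.
#' @param thresholds Named vector `c(green = ..., yellow = ...)`.
#' @return Character vector of labels (`"green"`, `"yellow"`, `"red"`).
#' @export
#' @examples
#' classify_contrast(c(0.05, 0.03, 0.0299))
classify_contrast <- function(value, thresholds = c(green = 0.05, yellow = 0.03)) {
  if (any(value < 0)) stop("`value` must be non-negative", call. = FALSE)
  if (thresholds[["green"]] <= thresholds[["yellow"]]) {
    stop("green threshold must exceed yellow threshold", call. = FALSE)
  }
  ifelse(value >= thresholds[["green"]], "green",
         ifelse(value >= thresholds[["yellow"]], "yellow", "red"))
}

#' Contrast-detail analysis of a phantom image
#'
#' Measures the contrast difference of each low-contrast hole and classifies
#' it into the green/yellow/red visibility bands. For every hole, `E` is the
#' mean signal over a concentric disc at 80% of the projected hole diameter
#' and `E0` the mean over a concentric annulus from 120% to 160% of the
#' projected diameter: concentric sampling is unbiased under the renderer's
#' symmetric PSF, and the inner margin keeps the measurement clear of the
#' blurred hole edge. The result is the contrast-detail distribution over
#' hole depth (contrast) and diameter (detail).
#'
#' @param image A [portal_image()].
#' @param phantom The `phantom_spec`.
#' @param geom The [imaging_geometry()].
#' @param thresholds Visibility thresholds, see [classify_contrast()].
#' @param roi_scales Measurement-geometry factors as fractions of the
#'   projected hole radius: `disc` (measurement disc), `ann_in`/`ann_out`
#'   (background annulus).
#' @return A `contrast_detail_result`: `measurements` (data frame with
#'   diameter, depth, E, E0, contrast_difference, label) and `counts`
#'   (named vector green/yellow/red).
#' @export
contrast_detail_distribution <- function(image, phantom, geom,
                                         thresholds = c(green = 0.05, yellow = 0.03),
                                         roi_scales = c(disc = 0.8,
                                                        ann_in = 1.2,
                                                        ann_out = 1.6)) {
  stopifnot(inherits(image, "portal_image"), inherits(phantom, "phantom_spec"),
            inherits(geom, "imaging_geometry"))
  M <- magnification(geom)
  xs <- image_x_mm(image)
  ys <- image_y_mm(image)
  h <- phantom$contrast_holes

  one <- function(i) {
    cx <- h$x[i] * M
    cy <- h$y[i] * M
    r <- h$diameter[i] / 2 * M
    r_out <- roi_scales[["ann_out"]] * r
    cols <- which(abs(xs - cx) <= r_out)
    rows <- which(abs(ys - cy) <= r_out)
    if (!length(cols) || !length(rows) ||
        cx - r_out < min(xs) || cx + r_out > max(xs) ||
        cy - r_out < min(ys) || cy + r_out > max(ys)) {
      stop(sprintf("hole ROI (d=%g mm at %g,%g) lies outside the image",
                   h$diameter[i], h$x[i], h$y[i]), call. = FALSE)
    }
    d2 <- outer((ys[rows] - cy)^2, (xs[cols] - cx)^2, `+`)
    sub <- image$pixels[rows, cols, drop = FALSE]
    disc <- d2 <= (roi_scales[["disc"]] * r)^2
    ann <- d2 >= (roi_scales[["ann_in"]] * r)^2 & d2 <= r_out^2
    if (!any(disc) || !any(ann)) {
      stop(sprintf("hole (d=%g mm) too small for the pixel spacing",
                   h$diameter[i]), call. = FALSE)
    }
    c(E = mean(sub[disc]), E0 = mean(sub[ann]))
  }

  m <- t(vapply(seq_len(nrow(h)), one, c(E = 0, E0 = 0)))
  cd <- contrast_difference(m[, "E"], m[, "E0"])
  label <- classify_contrast(cd, thresholds)
  measurements <- data.frame(
    diameter = h$diameter, depth = h$depth, x = h$x, y = h$y,
    E = m[, "E"], E0 = m[, "E0"], contrast_difference = cd, label = label,
    stringsAsFactors = FALSE
  )
  counts <- c(green = sum(label == "green"), yellow = sum(label == "yellow"),
              red = sum(label == "red"))
  structure(
    list(measurements = measurements, counts = counts,
         thresholds = thresholds, beam_mode = image$beam_mode),
    class = "contrast_detail_result"
  )
}

#' @export
print.contrast_detail_result <- function(x, ...) {
  cat(sprintf(
    "<contrast_detail_result> beam=%s, %d holes: %d green, %d yellow, %d red\n",
    x$beam_mode, nrow(x$measurements),
    x$counts[["green"]], x$counts[["yellow"]], x$counts[["red"]]
  ))
  invisible(x)
}
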