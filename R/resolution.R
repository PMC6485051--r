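#' Bar-pattern region of interest
#'
#' Describes where a lamella block lies in an image: the row band to average
#' across (transverse to the bars) and the bar pattern's start, period and
#' count along x, in imager-plane mm. [region_contrast()] converts these to
#' pixel columns through the image's coordinate convention.
#'
#' @param rows Integer vector of pixel rows to average over.
#' @param x_start_mm Imager-plane x of the first bar's leading edge (mm).
#' @param period_mm Bar + gap period at the imager plane (mm).
#' @param n_periods Number of full periods in the pattern.
#' @return A `bar_roi` object.
#' @export
bar_roi <- function(rows, x_start_mm, period_mm, n_periods) {
  if (period_mm <= 0 || n_periods < 1) {
    stop("`period_mm` must be positive and `n_periods` >= 1", call. = FALSE)
  }
  structure(list(rows = as.integer(rows), x_start_mm = x_start_mm,
                 period_mm = period_mm, n_periods = as.integer(n_periods)),
            class = "bar_roi")
}

#' Square-wave contrast of a bar region
#'
#' Estimates the image contrast \eqn{k = (\max - \min) / (\max + \min)} of a
#' bar pattern. The region is first averaged transverse to the bars (row
#' means), then split into its periods; the maximum and minimum grey level of
#' each full period are located and averaged across periods. This per-period
#' averaging is the robust reading of a "maximum and minimum grayscale"
#' contrast under noise: a single global extremum would be biased upward by
#' noise, while per-period extrema averaged over several periods converge on
#' the modulation amplitude. When four or more periods are available the
#' outermost period at each end is dropped to avoid edge effects of the
#' finite pattern.
#'
#' @param image A [portal_image()].
#' @param roi A [bar_roi()].
#' @param drop_edge_periods Drop first/last period when enough are available
#'   (default `TRUE`).
#' @return A `region_contrast` object: `max_level`, `min_level`, `k`,
#'   `n_periods_used`.
#' @export
region_contrast <- function(image, roi, drop_edge_periods = TRUE) {
  stopifnot(inherits(image, "portal_image"), inherits(roi, "bar_roi"))
  if (min(roi$rows) < 1 || max(roi$rows) > nrow(image$pixels)) {
    stop("`roi` rows lie outside the image", call. = FALSE)
  }
  xs <- image_x_mm(image)
  x_end <- roi$x_start_mm + roi$n_periods * roi$period_mm
  if (roi$x_start_mm < min(xs) - image$pixel_spacing / 2 ||
      x_end > max(xs) + image$pixel_spacing / 2) {
    stop("`roi` extends outside the image", call. = FALSE)
  }
  cols <- which(xs >= roi$x_start_mm & xs < x_end)
  profile <- colMeans(image$pixels[roi$rows, cols, drop = FALSE])
  px <- xs[cols]
  period_idx <- floor((px - roi$x_start_mm) / roi$period_mm)
  per <- split(profile, period_idx)
  per <- per[vapply(per, length, 0L) >= 2]
  if (length(per) >= 4 && drop_edge_periods) {
    per <- per[-c(1, length(per))]
  }
  if (length(per) < 2) {
    stop("insufficient sampling: fewer than 2 usable bar periods in the ROI",
         call. = FALSE)
  }
  max_level <- mean(vapply(per, max, 0))
  min_level <- mean(vapply(per, min, 0))
  if (max_level + min_level <= 0) {
    stop("degenerate region: zero total signal", call. = FALSE)
  }
  structure(
    list(max_level = max_level, min_level = min_level,
         k = (max_level - min_level) / (max_level + min_level),
         n_periods_used = length(per)),
    class = "region_contrast"
  )
}

#' Bar-pattern MTF curve of a phantom image
#'
#' Measures the square-wave contrast of every horizontal lamella block,
#' divides by the object contrast (the contrast of the ideal, undegraded
#' two-level transmission pattern, taken from the render metadata or supplied
#' explicitly), and normalizes the resulting transfer ratios to the lowest
#' spatial frequency. Frequencies are reported in phantom-plane lp/mm: block
#' positions are projected to the imager by the geometric magnification
#' before profile extraction, and a phantom frequency `f` is measured at
#' `f / M` on the imager. The square-wave contrast ratio is used directly as
#' the MTF (no square-to-sine conversion), which is the bar-pattern
#' convention this analysis follows throughout.
#'
#' Blocks whose projected period falls below 2 pixels cannot be sampled and
#' are excluded (flagged in the returned table). The critical and limiting
#' frequencies f50/f10 -- the frequencies at which the relative MTF first
#' falls to 50% and 10% -- are attached, with censoring flags when the
#' measured curve never falls that far.
#'
#' @param image A [portal_image()] of the phantom.
#' @param phantom The `phantom_spec` used to render (or describing) it.
#' @param geom The [imaging_geometry()].
#' @param object_contrast Object-plane contrast `k` of the lamella pattern;
#'   defaults to the value derived from the image's ideal-level metadata.
#' @param transverse_fraction Fraction of the block height averaged across
#'   (default 0.7, keeping clear of the block's ends).
#' @return An `mtf_curve`: `table` (frequency, width, mtf_raw, mtf_relative,
#'   period_px, excluded), `f50`, `f10`, `f50_censored`, `f10_censored`.
#' @export
compute_mtf_curve <- function(image, phantom, geom, object_contrast = NULL,
                              transverse_fraction = 0.7) {
  stopifnot(inherits(image, "portal_image"), inherits(phantom, "phantom_spec"),
            inherits(geom, "imaging_geometry"))
  if (is.null(object_contrast)) {
    lv <- image$meta$ideal_levels
    if (is.null(lv)) {
      stop("no `object_contrast` given and the image metadata has no ideal levels",
           call. = FALSE)
    }
    object_contrast <- (lv$background - lv$bar) / (lv$background + lv$bar)
  }
  if (object_contrast <= 0) {
    stop("`object_contrast` must be positive", call. = FALSE)
  }
  M <- magnification(geom)
  s <- image$pixel_spacing
  ys <- image_y_mm(image)
  blocks <- phantom$lamella_blocks
  blocks <- blocks[blocks$orientation == "horizontal", ]
  blocks <- blocks[order(blocks$frequency), ]

  res <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    period_px <- 2 * b$width * M / s
    if (period_px < 2) {
      return(data.frame(frequency = b$frequency, width = b$width,
                        mtf_raw = NA_real_, period_px = period_px,
                        excluded = TRUE))
    }
    half <- transverse_fraction * b$height / 2 * M
    rows <- which(ys >= b$y_center * M - half & ys <= b$y_center * M + half)
    if (!length(rows)) {
      stop(sprintf("lamella block at %.2f lp/mm lies outside the image",
                   b$frequency), call. = FALSE)
    }
    roi <- bar_roi(rows, x_start_mm = b$x_start * M,
                   period_mm = 2 * b$width * M, n_periods = b$n_periods)
    rc <- region_contrast(image, roi)
    data.frame(frequency = b$frequency, width = b$width,
               mtf_raw = rc$k / object_contrast, period_px = period_px,
               excluded = FALSE)
  })
  tab <- do.call(rbind, res)
  usable <- !tab$excluded
  if (!any(usable)) stop("no lamella block is resolvable at this pixel spacing",
                         call. = FALSE)
  base <- tab$mtf_raw[which(usable)[1]]
  if (base <= 0) stop("zero contrast at the lowest frequency", call. = FALSE)
  tab$mtf_relative <- tab$mtf_raw / base

  rel <- tab[usable, ]
  f50 <- characteristic_frequency(rel, 0.5)
  f10 <- characteristic_frequency(rel, 0.1)
  structure(
    list(table = tab,
         f50 = as.numeric(f50), f10 = as.numeric(f10),
         f50_censored = isTRUE(attr(f50, "censored")),
         f10_censored = isTRUE(attr(f10, "censored")),
         object_contrast = object_contrast, beam_mode = image$beam_mode),
    class = "mtf_curve"
  )
}

#' @export
print.mtf_curve <- function(x, ...) {
  cat(sprintf(
    "<mtf_curve> beam=%s, %d frequencies: f50 = %.3f lp/mm%s, f10 = %.3f lp/mm%s\n",
    x$beam_mode, sum(!x$table$excluded),
    x$f50, if (x$f50_censored) " (censored)" else "",
    x$f10, if (x$f10_censored) " (censored)" else ""
  ))
  invisible(x)
}

#' Frequency at which the relative MTF falls to a level
#'
#' Returns the lowest frequency at which the relative MTF first crosses
#' `level`, by linear interpolation between the bracketing measured
#' frequencies (f50 for `level = 0.5`, f10 for `level = 0.1`). If the
#' measured curve never falls below the level, the highest measured frequency
#' is returned with attribute `censored = TRUE`: the true crossing lies
#' beyond the measured range. Non-monotone (noisy) curves are handled by
#' taking the first downward crossing.
#'
#' @param curve An `mtf_curve`, or a data frame with columns `frequency` and
#'   `mtf_relative` (ascending frequency).
#' @param level Fraction in (0, 1).
#' @return Frequency in lp/mm, with logical attribute `"censored"`.
#' @export
#' @examples
#' characteristic_frequency(
#'   data.frame(frequency = c(0.5, 1), mtf_relative = c(0.8, 0.4)), 0.5)
characteristic_frequency <- function(curve, level) {
  if (length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must be a single value in (0, 1)", call. = FALSE)
  }
  tab <- if (inherits(curve, "mtf_curve")) {
    curve$table[!curve$table$excluded, ]
  } else {
    as.data.frame(curve)
  }
  if (!all(c("frequency", "mtf_relative") %in% names(tab)) || nrow(tab) < 2) {
    stop("`curve` needs >= 2 points with `frequency` and `mtf_relative`",
         call. = FALSE)
  }
  f <- tab$frequency
  v <- tab$mtf_relative
  hit <- which(v <= level)
  if (!length(hit)) {
    return(structure(f[length(f)], censored = TRUE))
  }
  j <- hit[1]
  if (j == 1 || v[j] == level) {
    return(structure(f[j], censored = FALSE))
  }
  out <- f[j - 1] + (v[j - 1] - level) / (v[j - 1] - v[j]) * (f[j] - f[j - 1])
  structure(out, censored = FALSE)
}
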