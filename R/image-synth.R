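#' Detector model
#'
#' Parametric model of the computed-radiography imaging chain. The energy
#' dependence of the real detector's response is folded into a
#' beam-mode-dependent Gaussian point-spread width and gain rather than a
#' physical absorbed-energy model: the aluminium-target beam, rich in
#' diagnostic-energy photons, is assigned a narrower PSF than the 6 MV beam,
#' which is the level of description the downstream MTF/contrast analyses can
#' test. The full-resolution canvas emulates a 2828 x 2320 pixel CR plate at
#' 0.125 mm pixel spacing; `scale` shrinks the canvas (and coarsens the
#' spacing) for desk-scale work.
#'
#' @param mode Optional beam mode (`"al_target"` or `"6mv"`); fills in the
#'   default PSF width for that beam quality (0.33 mm and 0.56 mm at the
#'   imager plane respectively, chosen so the synthetic critical frequencies
#'   fall in the regime reported for CR portal imaging).
#' @param psf_sigma_mm Gaussian PSF sigma at the imager plane (mm, >= 0).
#' @param gain Detector signal for unit transmission (counts).
#' @param poisson_scale Quantum-noise variance scale (counts of variance per
#'   count of signal); 0 disables the Poisson component.
#' @param gaussian_sigma Additive electronic-noise sigma (counts); 0 disables.
#' @param scale Canvas scale factor in (0, 1].
#' @param bit_depth Output bit depth (default 16).
#' @return A `detector_model` object with derived `n_rows`, `n_cols` and
#'   `pixel_spacing` (mm/pixel).
#' @export
detector_model <- function(mode = NULL, psf_sigma_mm = NULL, gain = 52000,
                           poisson_scale = 4, gaussian_sigma = 50,
                           scale = 1, bit_depth = 16) {
  if (is.null(psf_sigma_mm)) {
    if (is.null(mode)) {
      stop("provide `psf_sigma_mm` or a beam `mode` with a default PSF",
           call. = FALSE)
    }
    mode <- match.arg(mode, c("al_target", "6mv"))
    psf_sigma_mm <- c(al_target = 0.33, `6mv` = 0.56)[[mode]]
  }
  if (psf_sigma_mm < 0 || gain <= 0 || poisson_scale < 0 || gaussian_sigma < 0) {
    stop("invalid detector parameters: psf_sigma_mm >= 0, gain > 0, noise >= 0",
         call. = FALSE)
  }
  if (scale <= 0 || scale > 1) stop("`scale` must be in (0, 1]", call. = FALSE)
  structure(
    list(mode = mode, psf_sigma_mm = psf_sigma_mm, gain = gain,
         poisson_scale = poisson_scale, gaussian_sigma = gaussian_sigma,
         scale = scale, bit_depth = bit_depth,
         n_rows = round(2320 * scale), n_cols = round(2828 * scale),
         pixel_spacing = 0.125 / scale),
    class = "detector_model"
  )
}

#' Portal image container
#'
#' A 2-D grayscale pixel matrix with imager-plane pixel spacing and beam-mode
#' metadata. Pixel (1, 1) is top-left; the imager-plane x coordinate of
#' column `j` is `(j - (ncol + 1) / 2) * pixel_spacing` mm and the y
#' coordinate of row `i` is `((nrow + 1) / 2 - i) * pixel_spacing` mm, so the
#' beam axis pierces the canvas centre. Images are stored non-inverted
#' (bright = high transmission); `inverted` is a display flag only and is
#' never applied before analysis.
#'
#' @param pixels Numeric matrix, values in `[0, 2^bit_depth - 1]`.
#' @param pixel_spacing mm per pixel at the imager plane (> 0).
#' @param beam_mode Beam-mode identifier.
#' @param inverted Display-inversion flag.
#' @param meta List of provenance metadata (seed, PSF, noise, ideal levels,
#'   geometry).
#' @return A `portal_image` object.
#' @export
portal_image <- function(pixels, pixel_spacing, beam_mode = NA_character_,
                         inverted = FALSE, meta = list()) {
  if (!is.matrix(pixels) || any(dim(pixels) < 1)) {
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  }
  if (pixel_spacing <= 0) stop("`pixel_spacing` must be > 0", call. = FALSE)
  if (any(pixels < 0) || any(pixels > 65535)) {
    stop("pixel values must lie in [0, 65535]", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing,
         beam_mode = beam_mode, inverted = inverted, meta = meta),
    class = "portal_image"
  )
}

#' @export
print.portal_image <- function(x, ...) {
  cat(sprintf(
    "<portal_image> %d x %d px @ %.4g mm/px, beam=%s, range [%g, %g]\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_spacing, x$beam_mode,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

# Imager-plane mm coordinates of pixel centres.
image_x_mm <- function(img) {
  nc <- ncol(img$pixels)
  (seq_len(nc) - (nc + 1) / 2) * img$pixel_spacing
}
image_y_mm <- function(img) {
  nr <- nrow(img$pixels)
  ((nr + 1) / 2 - seq_len(nr)) * img$pixel_spacing
}

#' Spectrum-weighted transmission of the phantom's material stacks
#'
#' Ideal (scatter-free) transmission for each distinct region of the phantom:
#' open beam, base plate, base + lamella bar, base + contrast element, and
#' base + element + each hole depth. The low-contrast "holes" are modelled as
#' regions of additional aluminium path equal to the printed depth, so the
#' measured contrast follows the exponential contrast-difference law exactly.
#'
#' @param phantom A `phantom_spec`.
#' @param beam A [beam_spectrum()].
#' @return Named list: `open`, `background`, `bar`, `element`, and `hole`, a
#'   named vector keyed by depth.
#' @export
region_transmissions <- function(phantom, beam) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(beam, "beam_spectrum"))
  mids <- spectrum_bin_mids(beam)
  w <- beam$weights / sum(beam$weights)
  mu_base <- attenuation_coefficient(phantom$base_material, mids)
  mu_el <- attenuation_coefficient(phantom$element_material, mids)
  mu_bar <- attenuation_coefficient(phantom$lamella_material, mids)
  trans <- function(path) sum(w * exp(-path))
  base_path <- mu_base * phantom$base_thickness
  el_path <- base_path + mu_el * phantom$element_thickness
  depths <- sort(unique(phantom$contrast_holes$depth))
  hole <- vapply(depths, function(d) trans(el_path + mu_el * d), 0)
  names(hole) <- as.character(depths)
  list(
    open = 1,
    background = trans(base_path),
    bar = trans(base_path + mu_bar * phantom$lamella_thickness),
    element = trans(el_path),
    hole = hole
  )
}

# Gaussian blur of a plain matrix, sigma in pixels.
blur_matrix <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  EBImage::gblur(m, sigma = sigma_px)
}

# Paint one lamella block onto the transmission matrix (in place semantics
# via return). xs/ys are phantom-plane mm coordinates of the pixel grid.
paint_block <- function(tr, block, xs, ys, bar_level) {
  len <- 2 * block$width * block$n_periods
  if (block$orientation == "horizontal") {
    cols <- which(xs >= block$x_start & xs < block$x_start + len)
    rows <- which(abs(ys - block$y_center) <= block$height / 2)
    if (!length(cols) || !length(rows)) return(tr)
    k <- floor((xs[cols] - block$x_start) / block$width)
    bar_cols <- cols[k %% 2 == 0]
    tr[rows, bar_cols] <- bar_level
  } else {
    # 45-degree pattern: bar index along u = (dx + dy) / sqrt(2)
    half_diag <- (len + block$height) / sqrt(2)
    cols <- which(xs >= block$x_start - block$height &
                    xs <= block$x_start + half_diag + block$height)
    rows <- which(abs(ys - block$y_center) <= half_diag)
    if (!length(cols) || !length(rows)) return(tr)
    dx <- xs[cols] - block$x_start
    dy <- ys[rows] - block$y_center
    u <- outer(dy, dx, function(a, b) (a + b) / sqrt(2))
    v <- outer(dy, dx, function(a, b) (a - b) / sqrt(2))
    inside <- u >= 0 & u < len & abs(v) <= block$height / 2
    bar <- inside & (floor(u / block$width) %% 2 == 0)
    sub <- tr[rows, cols]
    sub[bar] <- bar_level
    tr[rows, cols] <- sub
  }
  tr
}

#' Render a synthetic portal image of the phantom
#'
#' Computes the ideal per-region transmission image (spectrum-weighted
#' Beer-Lambert through the phantom's material stacks), projects the phantom
#' layout to the imager plane by the geometric magnification, convolves with
#' the detector's Gaussian PSF, applies quantum (scaled-Poisson) and
#' electronic (Gaussian) noise, and quantises to the detector bit depth.
#' Output is bit-identical for identical inputs and seed.
#'
#' @param phantom A `phantom_spec`.
#' @param beam A [beam_spectrum()].
#' @param geom An [imaging_geometry()].
#' @param det A [detector_model()].
#' @param seed Integer RNG seed recorded in the image metadata.
#' @param quantize Quantise to integer grey levels (default `TRUE`). Turning
#'   quantisation off retains the continuous signal, which is useful when
#'   comparing against analytic transfer-function predictions.
#' @return A [portal_image()]. `meta$ideal_levels` records the noise-free
#'   region signal levels used by the MTF analysis as object contrast.
#' @export
render_phantom_image <- function(phantom, beam, geom, det, seed = 1L,
                                 quantize = TRUE) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(beam, "beam_spectrum"),
            inherits(geom, "imaging_geometry"), inherits(det, "detector_model"))
  fp <- phantom$footprint
  half_field <- geom$field_size * 10 / 2  # cm -> mm, half extent
  if (max(abs(fp[1:2])) > half_field[1] || max(abs(fp[3:4])) > half_field[2]) {
    stop("field is smaller than the phantom footprint", call. = FALSE)
  }
  M <- magnification(geom)
  s <- det$pixel_spacing
  nr <- det$n_rows
  nc <- det$n_cols
  # phantom-plane coordinates of each pixel centre
  xs <- ((seq_len(nc) - (nc + 1) / 2) * s) / M
  ys <- (((nr + 1) / 2 - seq_len(nr)) * s) / M

  lv <- region_transmissions(phantom, beam)
  leak <- 0.02  # out-of-field transmission (collimator leakage)
  tr <- matrix(leak, nr, nc)
  in_x <- abs(xs) <= half_field[1]
  in_y <- abs(ys) <= half_field[2]
  tr[in_y, in_x] <- lv$open
  bg_rows <- which(ys >= fp[3] & ys <= fp[4])
  bg_cols <- which(xs >= fp[1] & xs <= fp[2])
  tr[bg_rows, bg_cols] <- lv$background
  er <- phantom$element_region
  tr[ys >= er[3] & ys <= er[4], xs >= er[1] & xs <= er[2]] <- lv$element

  b <- phantom$lamella_blocks
  for (i in seq_len(nrow(b))) {
    tr <- paint_block(tr, b[i, ], xs, ys, lv$bar)
  }
  h <- phantom$contrast_holes
  for (i in seq_len(nrow(h))) {
    r <- h$diameter[i] / 2
    cols <- which(abs(xs - h$x[i]) <= r)
    rows <- which(abs(ys - h$y[i]) <= r)
    if (!length(cols) || !length(rows)) next
    mask <- outer((ys[rows] - h$y[i])^2, (xs[cols] - h$x[i])^2, `+`) <= r^2
    sub <- tr[rows, cols, drop = FALSE]
    sub[mask] <- lv$hole[[as.character(h$depth[i])]]
    tr[rows, cols] <- sub
  }

  signal <- det$gain * blur_matrix(tr, det$psf_sigma_mm / s)

  if (det$poisson_scale > 0 || det$gaussian_sigma > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    if (det$poisson_scale > 0) {
      lambda <- pmax(signal, 0) / det$poisson_scale
      signal <- matrix(stats::rpois(length(lambda), lambda), nr, nc) *
        det$poisson_scale
    }
    if (det$gaussian_sigma > 0) {
      signal <- signal + stats::rnorm(length(signal), 0, det$gaussian_sigma)
    }
  }
  maxval <- 2^det$bit_depth - 1
  if (quantize) signal <- round(signal)
  signal <- pmin(pmax(signal, 0), maxval)

  portal_image(
    signal, pixel_spacing = s, beam_mode = beam$mode,
    meta = list(
      seed = seed, psf_sigma_mm = det$psf_sigma_mm,
      noise = c(poisson_scale = det$poisson_scale,
                gaussian_sigma = det$gaussian_sigma),
      gain = det$gain, magnification = M, scale = det$scale,
      quantized = quantize,
      ideal_levels = lapply(lv, function(v) v * det$gain)
    )
  )
}

#' Render a standalone bar-pattern image
#'
#' A single square-wave bar pattern (no phantom, no spectrum): `n_periods`
#' dark bars of the given width on a bright background, optionally blurred by
#' a Gaussian PSF. Bar edges are aligned with the centred mm grid used by
#' [portal_image()], and the pattern is horizontally centred. Used to
#' characterise the bar-pattern MTF estimator against analytic
#' transfer-function predictions.
#'
#' @param width_mm Bar (= gap) width in mm.
#' @param psf_sigma_mm Gaussian PSF sigma (mm).
#' @param pixel_spacing mm per pixel.
#' @param n_periods Number of bar/gap periods.
#' @param hi,lo Background and bar signal levels (counts).
#' @param height_mm Pattern height (mm).
#' @param pad_mm Clear margin around the pattern (mm).
#' @param quantize Quantise to integer grey levels.
#' @return A [portal_image()] whose `meta` records the pattern layout
#'   (`x_start_mm`, `width_mm`, `n_periods`, `hi`, `lo`).
#' @export
render_bar_pattern <- function(width_mm, psf_sigma_mm = 0,
                               pixel_spacing = 0.025, n_periods = 8,
                               hi = 40000, lo = 8000, height_mm = 5,
                               pad_mm = NULL, quantize = TRUE) {
  if (width_mm <= 0) stop("`width_mm` must be positive", call. = FALSE)
  len <- 2 * width_mm * n_periods
  if (is.null(pad_mm)) pad_mm <- max(2, 8 * psf_sigma_mm, 2 * width_mm)
  nc <- 2 * ceiling((len / 2 + pad_mm) / pixel_spacing)
  nr <- 2 * ceiling((height_mm / 2 + pad_mm) / pixel_spacing)
  xs <- (seq_len(nc) - (nc + 1) / 2) * pixel_spacing
  ys <- ((nr + 1) / 2 - seq_len(nr)) * pixel_spacing
  x_start <- -len / 2
  m <- matrix(hi, nr, nc)
  cols <- which(xs >= x_start & xs < x_start + len)
  rows <- which(abs(ys) <= height_mm / 2)
  k <- floor((xs[cols] - x_start) / width_mm)
  m[rows, cols[k %% 2 == 0]] <- lo
  m <- blur_matrix(m, psf_sigma_mm / pixel_spacing)
  if (quantize) m <- round(m)
  m <- pmin(pmax(m, 0), 65535)
  portal_image(
    m, pixel_spacing = pixel_spacing, beam_mode = "bar_target",
    meta = list(x_start_mm = x_start, width_mm = width_mm,
                n_periods = n_periods, hi = hi, lo = lo,
                height_mm = height_mm, psf_sigma_mm = psf_sigma_mm,
                quantized = quantize)
  )
}

#' Display-inverted copy of an image
#'
#' The convention for presenting portal images is inverted grayscale (dark =
#' high transmission). This returns a copy with flipped grey levels and the
#' `inverted` flag set; analyses always operate on non-inverted images.
#'
#' @param img A [portal_image()].
#' @return The inverted [portal_image()].
#' @export
invert_for_display <- function(img) {
  stopifnot(inherits(img, "portal_image"))
  maxval <- 65535
  portal_image(maxval - img$pixels, img$pixel_spacing, img$beam_mode,
               inverted = !img$inverted, meta = img$meta)
}
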