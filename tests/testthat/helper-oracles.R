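# Independent oracles and shared fixtures for the test suite.

# Continuous blurred bar-pattern profile: a square wave of `n_periods` dark
# bars (level `lo`) of width `width` on a bright background (`hi`),
# convolved with a Gaussian of the given sigma. Closed form via the normal
# CDF -- independent of the package's renderer and blur path.
oracle_bar_value <- function(x, x_start, width, n_periods, hi, lo, sigma) {
  v <- 0
  for (k in seq_len(n_periods)) {
    a <- x_start + (2 * k - 2) * width
    v <- v + pnorm((x - a) / sigma) - pnorm((x - a - width) / sigma)
  }
  hi - (hi - lo) * v
}

# Direct-convolution square-wave response: per-period extrema of the
# continuous blurred profile over the interior periods (the same periods the
# estimator uses), averaged, expressed as image/object contrast ratio.
oracle_square_mtf <- function(width, sigma, n_periods = 8, hi = 40000,
                              lo = 8000, dx = 0.001) {
  x_start <- -n_periods * width
  ks <- 2:(n_periods - 1)
  mins <- maxs <- numeric(length(ks))
  for (i in seq_along(ks)) {
    x <- seq(x_start + (ks[i] - 1) * 2 * width, x_start + ks[i] * 2 * width,
             by = dx)
    v <- oracle_bar_value(x, x_start, width, n_periods, hi, lo, sigma)
    mins[i] <- min(v)
    maxs[i] <- max(v)
  }
  k_img <- (mean(maxs) - mean(mins)) / (mean(maxs) + mean(mins))
  k_img / ((hi - lo) / (hi + lo))
}

# Measure one rendered bar pattern with the package estimator, as the raw
# image/object contrast ratio. The transverse band keeps 3.5 sigma clear of
# the pattern's vertical ends so only in-pattern rows are averaged.
measure_bar_mtf <- function(width, sigma, n_periods = 8, hi = 40000,
                            lo = 8000, height_mm = 8) {
  img <- render_bar_pattern(width, psf_sigma_mm = sigma,
                            n_periods = n_periods, hi = hi, lo = lo,
                            height_mm = height_mm)
  nr <- nrow(img$pixels)
  ys <- ((nr + 1) / 2 - seq_len(nr)) * img$pixel_spacing
  band <- max(height_mm / 2 - 3.5 * sigma, 1)
  roi <- bar_roi(which(abs(ys) <= band), img$meta$x_start_mm,
                 2 * width, n_periods)
  region_contrast(img, roi)$k / ((hi - lo) / (hi + lo))
}

# Dense-grid brute-force 1-D gamma: evaluated curve linearly interpolated at
# `spacing` (default 0.01 mm), exhaustive minimisation. Independent of
# gamma_1d()'s resampling machinery.
oracle_gamma_dense <- function(ref, ev, dose_tol_pct = 3, dta = 3,
                               spacing = 0.01) {
  grid <- seq(min(ev$positions), max(ev$positions), by = spacing)
  ed <- approx(ev$positions, ev$dose, xout = grid)$y
  dd <- dose_tol_pct / 100 * max(ref$dose)
  vapply(seq_along(ref$positions), function(i) {
    sel <- abs(grid - ref$positions[i]) <= 3 * dta
    if (!any(sel)) sel <- which.min(abs(grid - ref$positions[i]))
    sqrt(min(((grid[sel] - ref$positions[i]) / dta)^2 +
               ((ed[sel] - ref$dose[i]) / dd)^2))
  }, 0)
}

# Full-resolution noiseless, PSF-free renders are used by several files;
# cache them for the run.
.render_cache <- new.env(parent = emptyenv())
cached_noiseless_render <- function(mode) {
  key <- paste0("noiseless_", mode)
  if (is.null(.render_cache[[key]])) {
    det <- detector_model(mode, psf_sigma_mm = 0, poisson_scale = 0,
                          gaussian_sigma = 0, scale = 1)
    .render_cache[[key]] <- render_phantom_image(
      default_ptw_phantom(), make_toy_spectrum(mode), imaging_geometry(),
      det, seed = 1L
    )
  }
  .render_cache[[key]]
}

# Flat dose profile helper (percent scale).
flat_profile <- function(level = 100, from = 0, to = 100, by = 2) {
  dose_profile(seq(from, to, by = by), rep(level, length(seq(from, to, by = by))),
               kind = "lateral", normalization = "max")
}
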