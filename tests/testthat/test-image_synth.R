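ph <- default_ptw_phantom()
geom <- imaging_geometry()
al <- make_toy_spectrum("al_target")

test_that("rendering is bit-reproducible for a fixed seed", {
  det <- detector_model("al_target", scale = 0.2)
  a <- render_phantom_image(ph, al, geom, det, seed = 11)
  b <- render_phantom_image(ph, al, geom, det, seed = 11)
  cc <- render_phantom_image(ph, al, geom, det, seed = 12)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, cc$pixels))
  # rendering must not disturb the session RNG stream
  set.seed(99); before <- runif(3)
  render_phantom_image(ph, al, geom, det, seed = 5)
  set.seed(99)
  expect_identical(runif(3), before)
})

test_that("an undegraded render is an exact two-level pattern in bar regions", {
  img <- cached_noiseless_render("al_target")
  lv <- img$meta$ideal_levels
  M <- magnification(geom)
  b <- ph$lamella_blocks[ph$lamella_blocks$width == 1, ]
  nr <- nrow(img$pixels)
  ys <- ((nr + 1) / 2 - seq_len(nr)) * img$pixel_spacing
  rows <- which(abs(ys - b$y_center * M) <= 3)
  roi <- bar_roi(rows, b$x_start * M, 2 * b$width * M, b$n_periods)
  rc <- region_contrast(img, roi)
  # quantisation is the only deviation from the ideal transmission levels
  expect_lt(abs(rc$max_level - lv$background), 0.5)
  expect_lt(abs(rc$min_level - lv$bar), 0.5)
})

test_that("a narrower PSF yields strictly higher bar contrast per frequency", {
  det_narrow <- detector_model(psf_sigma_mm = 0.2, poisson_scale = 0,
                               gaussian_sigma = 0, scale = 0.5)
  det_wide <- detector_model(psf_sigma_mm = 0.6, poisson_scale = 0,
                             gaussian_sigma = 0, scale = 0.5)
  img_n <- render_phantom_image(ph, al, geom, det_narrow)
  img_w <- render_phantom_image(ph, al, geom, det_wide)
  mtf_n <- compute_mtf_curve(img_n, ph, geom)$table
  mtf_w <- compute_mtf_curve(img_w, ph, geom)$table
  keep <- !mtf_n$excluded
  expect_true(all(mtf_n$mtf_raw[keep] >= mtf_w$mtf_raw[keep]))
  # strictly higher wherever the wider PSF has visibly cut the response
  # (where both transfer ~everything, quantisation ties the two readings)
  strict <- keep & mtf_w$mtf_raw < 0.99 & mtf_n$frequency <= 1
  expect_true(any(strict))
  expect_true(all(mtf_n$mtf_raw[strict] > mtf_w$mtf_raw[strict]))
})

test_that("rendering refuses a field smaller than the phantom footprint", {
  small <- imaging_geometry(95.2, 110, field_size = c(10, 10))
  det <- detector_model("al_target", scale = 0.2)
  expect_error(render_phantom_image(ph, al, small, det), "footprint")
})

test_that("the extended phantom variant renders its diagonal blocks", {
  det <- detector_model("al_target", psf_sigma_mm = 0, poisson_scale = 0,
                        gaussian_sigma = 0, scale = 0.5)
  ph14 <- default_ptw_phantom("extended")
  img11 <- render_phantom_image(ph, al, geom, det)
  img14 <- render_phantom_image(ph14, al, geom, det)
  expect_false(identical(img11$pixels, img14$pixels))
  # diagonal duplicates do not change the MTF read from the horizontal sets
  m11 <- compute_mtf_curve(img11, ph, geom)
  m14 <- compute_mtf_curve(img14, ph14, geom)
  expect_equal(m14$table$mtf_raw, m11$table$mtf_raw)
})

test_that("dose-curve pairs realise the stated perturbation exactly", {
  p0 <- make_dose_curve_pair("pdd", c(0, 0, 0))
  expect_identical(p0$evaluated$dose, p0$reference$dose)
  expect_identical(p0$evaluated$positions, p0$reference$positions)

  p3 <- make_dose_curve_pair("lateral", c(3, 0, 0))
  expect_equal(p3$evaluated$dose, 1.03 * p3$reference$dose)

  ps <- make_dose_curve_pair("pdd", c(0, 2, 0))
  expect_equal(ps$evaluated$positions, ps$reference$positions + 2)
  expect_equal(ps$evaluated$dose, ps$reference$dose)

  # noise is seeded and reproducible
  n1 <- make_dose_curve_pair("pdd", c(0, 0, 0.5), seed = 3)
  n2 <- make_dose_curve_pair("pdd", c(0, 0, 0.5), seed = 3)
  expect_identical(n1$evaluated$dose, n2$evaluated$dose)
  expect_false(identical(n1$evaluated$dose, n1$reference$dose))

  # the reference PDD builds up then falls off, max normalized to 100
  expect_equal(max(p0$reference$dose), 100)
  dmax_at <- p0$reference$positions[which.max(p0$reference$dose)]
  expect_gt(dmax_at, 5)
  expect_lt(dmax_at, 40)
})

test_that("display inversion is a flagged view, not an analysis transform", {
  det <- detector_model("al_target", scale = 0.15)
  img <- render_phantom_image(ph, al, geom, det)
  inv <- invert_for_display(img)
  expect_true(inv$inverted)
  expect_identical(inv$pixels, 65535 - img$pixels)
})
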