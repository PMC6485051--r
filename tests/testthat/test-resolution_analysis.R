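test_that("region contrast matches closed forms on constructed patterns", {
  # exact two-level pattern at 3000/1000 -> k = 0.5
  img <- render_bar_pattern(4, psf_sigma_mm = 0, pixel_spacing = 1,
                            n_periods = 4, hi = 3000, lo = 1000,
                            height_mm = 6)
  rows <- which(abs(((nrow(img$pixels) + 1) / 2 - seq_len(nrow(img$pixels)))) <= 2)
  roi <- bar_roi(rows, img$meta$x_start_mm, 8, 4)
  rc <- region_contrast(img, roi)
  expect_equal(rc$k, 0.5)
  expect_equal(rc$max_level, 3000)
  expect_equal(rc$min_level, 1000)

  # uniform region -> k = 0
  flat <- portal_image(matrix(500, 10, 64), pixel_spacing = 1)
  rc0 <- region_contrast(flat, bar_roi(1:10, -30, 16, 3))
  expect_equal(rc0$k, 0)

  # sinusoid of amplitude a about mean m, sampled at its extrema -> k = a/m
  m <- 2000; a <- 300; period <- 20
  nc <- 121  # odd width puts pixel centres on integer mm, sampling the extrema
  x <- (seq_len(nc) - (nc + 1) / 2)  # spacing 1 mm
  x0 <- -50
  px <- matrix(m + a * cos(2 * pi * (x - x0) / period), 4, nc, byrow = TRUE)
  sine <- portal_image(px, pixel_spacing = 1)
  rc_s <- region_contrast(sine, bar_roi(1:4, x0, period, 5))
  expect_equal(rc_s$k, a / m)
})

test_that("region contrast rejects unusable regions", {
  img <- render_bar_pattern(2, pixel_spacing = 0.5, n_periods = 4)
  expect_error(region_contrast(img, bar_roi(1:4, -4, 4, 1)), "insufficient")
  expect_error(region_contrast(img, bar_roi(10^6, -4, 4, 4)), "outside")
  expect_error(region_contrast(img, bar_roi(1:4, 10^4, 4, 4)), "outside")
})

test_that("characteristic frequency interpolates the first downward crossing", {
  # exact sample hit
  c1 <- data.frame(frequency = c(0.125, 0.5), mtf_relative = c(1, 0.5))
  expect_equal(as.numeric(characteristic_frequency(c1, 0.5)), 0.5)
  # closed-form linear interpolation
  c2 <- data.frame(frequency = c(0.5, 1.0), mtf_relative = c(0.8, 0.4))
  expect_equal(as.numeric(characteristic_frequency(c2, 0.5)), 0.875)
  # censoring: curve never falls below the level
  c3 <- data.frame(frequency = c(0.5, 1, 2), mtf_relative = c(1, 0.8, 0.45))
  f10 <- characteristic_frequency(c3, 0.1)
  expect_equal(as.numeric(f10), 2)
  expect_true(attr(f10, "censored"))
  # non-monotone curve: first crossing wins
  c4 <- data.frame(frequency = 1:4, mtf_relative = c(1, 0.4, 0.6, 0.2))
  expect_equal(as.numeric(characteristic_frequency(c4, 0.5)),
               1 + 0.5 / 0.6)
  expect_error(characteristic_frequency(c2, 1.5), "in \\(0, 1\\)")
  expect_error(characteristic_frequency(c2[1, ], 0.5), ">= 2 points")
})

test_that("bar-pattern MTF agrees with the direct-convolution response", {
  # spot check; the full sigma sweep runs in the acceptance suite
  for (w in c(1, 0.5)) {
    meas <- measure_bar_mtf(w, sigma = 0.3)
    orc <- oracle_square_mtf(w, sigma = 0.3)
    expect_lt(abs(meas / orc - 1), 0.02)
  }
})

test_that("a wider PSF degrades the whole measured curve", {
  for (w in c(1, 0.5, 0.35)) {
    expect_lt(measure_bar_mtf(w, sigma = 0.45), measure_bar_mtf(w, sigma = 0.15))
  }
})

test_that("relative MTF is anchored at the lowest frequency and f50 <= f10", {
  ph <- default_ptw_phantom()
  geom <- imaging_geometry()
  det <- detector_model("al_target", scale = 0.35)
  img <- render_phantom_image(ph, make_toy_spectrum("al_target"), geom, det,
                              seed = 4)
  m <- compute_mtf_curve(img, ph, geom)
  usable <- !m$table$excluded
  expect_identical(m$table$mtf_relative[which(usable)[1]], 1)
  expect_true(all(m$table$mtf_relative[usable] >= 0))
  if (!m$f50_censored && !m$f10_censored) {
    expect_lte(m$f50, m$f10)
  }
  # blocks below the sampling limit are excluded, not fabricated
  expect_true(all(m$table$period_px[m$table$excluded] < 2))
})
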