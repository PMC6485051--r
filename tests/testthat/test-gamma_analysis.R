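test_that("profile normalization scales the stated reference feature to 100", {
  p <- dose_profile(c(0, 10, 20, 30), c(1, 2, 4, 2))
  n <- normalize_profile(p, "max")
  expect_equal(n$dose, c(25, 50, 100, 50))
  # idempotent on an already-normalized curve
  expect_equal(normalize_profile(n, "max")$dose, n$dose)

  lat <- dose_profile(c(-10, 0, 10), c(1.8, 2.0, 1.9), kind = "lateral")
  nc <- normalize_profile(lat, "cax")
  expect_equal(nc$dose[2], 100)

  expect_error(normalize_profile(dose_profile(1:3, c(0, 0, 0))), "degenerate")
  off_axis <- dose_profile(c(5, 10), c(1, 2), kind = "lateral")
  expect_error(normalize_profile(off_axis, "cax"), "position 0")
})

test_that("resampling is exact linear interpolation with preserved endpoints", {
  ramp <- dose_profile(c(0, 10), c(0, 50))
  r <- resample_evaluated(ramp, 1)
  expect_equal(r$positions, 0:10)
  expect_equal(r$dose, 5 * (0:10))

  # native-grid resampling recovers the original values
  p <- dose_profile(seq(0, 20, 2), sqrt(seq(0, 20, 2) + 1))
  expect_equal(resample_evaluated(p, 2)$dose, p$dose)

  # non-multiple span: the end position is appended
  odd <- dose_profile(c(0, 2.5), c(0, 5))
  expect_equal(resample_evaluated(odd, 1)$positions, c(0, 1, 2, 2.5))

  expect_error(resample_evaluated(dose_profile(1, 2), 1), "single-point")
  expect_error(dose_profile(c(0, 0, 1), c(1, 1, 1)), "increasing")
})

test_that("gamma reproduces the analytic flat-curve cases", {
  ref <- flat_profile()
  expect_equal(gamma_1d(ref, ref)$gamma, rep(0, length(ref$positions)))

  plus3 <- flat_profile(103)
  g3 <- gamma_1d(ref, plus3)
  expect_equal(g3$gamma, rep(1, length(ref$positions)))
  expect_equal(g3$pass_fraction, 1)

  plus6 <- flat_profile(106)
  g6 <- gamma_1d(ref, plus6)
  expect_equal(g6$gamma, rep(2, length(ref$positions)))
  expect_equal(g6$pass_fraction, 0)

  # doubling the dose tolerance halves gamma on dose-only deviations
  g6loose <- gamma_1d(ref, plus6, gamma_criteria(dose_tolerance = 6))
  expect_equal(g6loose$gamma, g6$gamma / 2)
})

test_that("a pure spatial shift is bounded by shift/dta plus grid error", {
  pair <- make_dose_curve_pair("lateral", c(0, 2, 0))
  crit <- gamma_criteria()
  g <- gamma_1d(pair$reference, pair$evaluated, crit)
  dense <- oracle_gamma_dense(pair$reference, pair$evaluated)
  # dense search: spatial compensation caps gamma at shift/dta
  expect_lte(max(dense), 2 / 3 + 0.01)
  # the 1 mm grid can add at most half a grid step of position and the
  # corresponding dose change
  slope <- max(abs(diff(pair$evaluated$dose) / diff(pair$evaluated$positions)))
  eps <- 0.5 * sqrt(1 / crit$dta^2 + (slope / 3)^2)
  expect_lte(g$max_gamma, max(dense) + eps)
  expect_gte(min(g$gamma), 0)
})

test_that("gamma enforces its contracts", {
  ref <- flat_profile()
  mismatched <- dose_profile(ref$positions, ref$dose, kind = "lateral",
                             normalization = "cax")
  expect_error(gamma_1d(ref, mismatched), "normalization")
  far <- dose_profile(c(500, 510), c(100, 100), kind = "lateral",
                      normalization = "max")
  expect_error(gamma_1d(ref, far), "overlap")
  expect_error(gamma_criteria(dose_tolerance = 0), "positive")
})

test_that("depth-dose pairs within 1.6% of maximum pass 3%/3 mm everywhere", {
  pair <- make_dose_curve_pair("pdd", c(1.6, 0, 0))
  g <- gamma_1d(pair$reference, pair$evaluated)
  expect_equal(g$pass_fraction, 1)
  expect_equal(g$max_dose_diff_percent, 1.6, tolerance = 1e-6)
  expect_lte(g$max_gamma, 1.6 / 3 + 1e-9)
})
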