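test_that("toy spectra concentrate weight as their beam quality dictates", {
  al <- make_toy_spectrum("al_target")
  mv <- make_toy_spectrum("6mv")

  expect_gt(low_energy_fraction(al), 0.3)
  expect_lt(low_energy_fraction(mv), 0.01)

  # the aluminium-target spectrum peaks at diagnostic energies
  mode_kev <- (al$bin_edges[-1] + al$bin_edges[-length(al$bin_edges)]) / 2
  expect_lt(mode_kev[which.max(al$weights)], 150)

  # determinism for fixed parameters
  expect_identical(make_toy_spectrum("al_target")$weights, al$weights)

  expect_error(make_toy_spectrum("cobalt"), "unknown beam mode")
})

test_that("low_energy_fraction computes exact pro-rata window overlaps", {
  # single bin entirely inside the window
  expect_equal(low_energy_fraction(beam_spectrum(c(50, 100), 1)), 1)
  # entirely above the window
  expect_equal(low_energy_fraction(beam_spectrum(c(200, 400), 1)), 0)
  # uniform weight on [0, 300]: closed-form overlap 125/300
  unif <- beam_spectrum(seq(0, 300, 10), rep(1, 30))
  expect_equal(low_energy_fraction(unif), 125 / 300)
  # straddling bin contributes pro-rata: bin [100, 200], window [25, 150]
  expect_equal(low_energy_fraction(beam_spectrum(c(100, 200), 1)), 0.5)
  expect_error(low_energy_fraction(unif, 150, 25), "below")
})

test_that("window fractions are additive over adjacent windows", {
  set.seed(42)
  for (i in 1:5) {
    edges <- sort(sample(1:500, 21))
    spec <- beam_spectrum(edges, runif(20))
    a <- 30; b <- 120; cc <- 260
    expect_equal(
      low_energy_fraction(spec, a, b) + low_energy_fraction(spec, b, cc),
      low_energy_fraction(spec, a, cc)
    )
  }
})

test_that("beam_spectrum enforces its invariants", {
  expect_error(beam_spectrum(c(1, 2), c(1, 1)), "length")
  expect_error(beam_spectrum(c(2, 1, 3), c(1, 1)), "increasing")
  expect_error(beam_spectrum(c(1, 2, 3), c(-1, 1)), "non-negative")
  expect_error(beam_spectrum(c(1, 2, 3), c(0, 0)), "positive")
})

test_that("electron survival falls smoothly to ~zero at the CSDA range", {
  f <- filter_spec("polystyrene", csda_range = 20)
  expect_equal(electron_survival(f, 0), 1)
  expect_lte(electron_survival(f, 20), 0.01)
  expect_lte(electron_survival(f, 25), 0.01)
  s <- electron_survival(f, c(8, 12, 16))
  expect_true(all(diff(s) < 0))
  expect_error(electron_survival(f, -1), ">= 0")
})

test_that("apply_filter is exact Beer-Lambert attenuation", {
  spec <- make_toy_spectrum("al_target", max_energy_kev = 500)
  f <- filter_spec("polystyrene")

  expect_equal(apply_filter(spec, f, 0)$weights, spec$weights)

  # constant mu = ln(2)/t0 halves every bin at thickness t0
  t0 <- 7
  fconst <- filter_spec("polystyrene", mu_of_E = function(E) {
    rep(log(2) / t0, length(E))
  })
  expect_equal(apply_filter(spec, fconst, t0)$weights, spec$weights / 2)

  # exponential law: doubling thickness squares each bin's transmission
  t1 <- apply_filter(spec, f, 5)$weights / spec$weights
  t2 <- apply_filter(spec, f, 10)$weights / spec$weights
  expect_equal(t2, t1^2)

  # bookkeeping: no filtered bin ever exceeds its unfiltered weight
  expect_true(all(apply_filter(spec, f, 3)$weights <= spec$weights))
})

test_that("filter sweep removes electrons while sparing low-energy photons", {
  spec <- make_toy_spectrum("al_target")
  sw <- filter_sweep(spec, c(0, 10, 20))
  expect_true(all(diff(sw$electron_fraction) < 0))
  expect_equal(sw$electron_fraction[1], 0.358)

  sw1 <- filter_sweep(spec, 0)
  expect_equal(sw1$electron_fraction, 0.358)
  expect_equal(sw1$photon_fraction, 0.642)

  sw2 <- filter_sweep(spec, seq(4, 20, 2))
  expect_lt(diff(range(sw2$low_energy_photon_fraction)), 0.02)

  expect_error(filter_sweep(spec, numeric(0)), "non-empty")
  expect_error(filter_sweep(spec, c(10, 5)), "ascending")
})

test_that("spectrum CSV round-trips on a uniform grid", {
  spec <- make_toy_spectrum("al_target", max_energy_kev = 300)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(spec, path)
  back <- read_spectrum(path)
  expect_equal(back$bin_edges, spec$bin_edges)
  expect_equal(back$weights, spec$weights)
})
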