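# Published bar widths and the frequencies printed for them (mixed 2- and
# 3-decimal rounding, exactly as printed).
ptw_table1 <- data.frame(
  width = c(4, 3, 2, 1.5, 1, 0.75, 0.5, 0.35, 0.25, 0.2, 0.15),
  printed = c("0.125", "0.167", "0.25", "0.33", "0.5",
              "0.67", "1", "1.43", "2", "2.5", "3.33"),
  stringsAsFactors = FALSE
)

test_that("lamella_frequency reproduces every printed width/frequency pair", {
  decimals <- vapply(ptw_table1$printed, function(s) {
    if (grepl("\\.", s)) nchar(sub(".*\\.", "", s)) else 0L
  }, 0L)
  freq <- lamella_frequency(ptw_table1$width)
  expect_equal(round(freq, decimals), as.numeric(ptw_table1$printed))
  expect_error(lamella_frequency(0), "positive")
  expect_error(lamella_frequency(-2), "positive")
})

test_that("default phantom has the published element structure", {
  ph <- default_ptw_phantom()
  expect_equal(nrow(ph$contrast_holes), 27)
  expect_equal(length(unique(ph$contrast_holes$diameter)), 6)
  expect_equal(length(unique(ph$contrast_holes$depth)), 5)
  expect_equal(length(unique(ph$lamella_blocks$frequency)), 11)
  expect_setequal(ph$lamella_blocks$width, ptw_table1$width)

  # depth series per diameter: the two largest diameters omit the deepest rows
  by_diam <- split(ph$contrast_holes$depth, ph$contrast_holes$diameter)
  expect_equal(sort(by_diam[["15"]]), c(0.5, 1, 2))
  expect_equal(sort(by_diam[["10"]]), c(0.5, 1, 2, 3.2))
  for (d in c("7", "4", "2", "1.1")) {
    expect_equal(sort(by_diam[[d]]), c(0.5, 1, 2, 3.2, 4.8))
  }
})

test_that("extended variant adds diagonal duplicates, not new frequencies", {
  ph <- default_ptw_phantom("extended")
  expect_equal(nrow(ph$lamella_blocks), 14)
  expect_equal(length(unique(ph$lamella_blocks$frequency)), 11)
  expect_equal(sum(ph$lamella_blocks$orientation == "diagonal"), 3)
  expect_equal(nrow(ph$contrast_holes), 27)
})

test_that("magnification is the SID/SSD ratio", {
  expect_equal(magnification(imaging_geometry(95.2, 110)), 110 / 95.2)
  expect_equal(magnification(imaging_geometry(100, 100)), 1)
  expect_error(imaging_geometry(ssd = 110, sid = 95.2), "sid >= ssd")
  expect_error(imaging_geometry(95.2, 110, field_size = -1), "positive")
})

test_that("projected bar period on a rendered image matches the magnification", {
  img <- cached_noiseless_render("al_target")
  ph <- default_ptw_phantom()
  geom <- imaging_geometry()
  M <- magnification(geom)
  b <- ph$lamella_blocks[1, ]  # 4 mm bars
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  ys <- ((nr + 1) / 2 - seq_len(nr)) * img$pixel_spacing
  row <- which.min(abs(ys - b$y_center * M))
  xs <- (seq_len(nc) - (nc + 1) / 2) * img$pixel_spacing
  len <- 2 * b$width * b$n_periods
  cols <- which(xs >= b$x_start * M & xs < (b$x_start + len) * M)
  profile <- img$pixels[row, cols]
  # falling edges (background -> bar) of the ideal two-level pattern
  lo <- min(profile); hi <- max(profile)
  edges <- which(diff(profile < (hi + lo) / 2) == 1)
  expect_equal(mean(diff(edges)) * img$pixel_spacing, 2 * b$width * M,
               tolerance = 0.01)
})

test_that("phantom specification round-trips through YAML", {
  ph <- default_ptw_phantom("extended")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(ph, path)
  back <- read_phantom_spec(path)
  expect_equal(back$lamella_blocks$width, ph$lamella_blocks$width)
  expect_equal(back$lamella_blocks$orientation, ph$lamella_blocks$orientation)
  expect_equal(back$contrast_holes, ph$contrast_holes)
  expect_equal(back$element_thickness, ph$element_thickness)
})
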