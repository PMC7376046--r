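test_that("population sampling honors counts, size distributions and seed", {
  expect_length(sample_population(0, 0, synth_config(), seed = 1), 0)

  cells <- sample_population(200, 10, synth_config(), seed = 7)
  expect_length(cells, 210)
  cls <- vapply(cells, `[[`, "", "class_label")
  expect_equal(sum(cls == "WBC"), 200)
  d <- vapply(cells, `[[`, 0, "diameter_um")
  expect_lt(abs(mean(d[cls == "WBC"]) - 11.5), 0.5)
  expect_gt(sd(d[cls == "CTC"]), sd(d[cls == "WBC"]))

  # diameter/pixel consistency and in-frame placement
  p <- synth_config()
  for (cell in cells) {
    expect_equal(cell$diameter_px, cell$diameter_um / p$pixel_scale_um)
    expect_true(cell$center_rc[1] >= 0 && cell$center_rc[1] <= p$shape[1] - 1)
    expect_true(cell$center_rc[2] >= 0 && cell$center_rc[2] <= p$shape[2] - 1)
  }

  expect_identical(sample_population(5, 5, synth_config(), seed = 3),
                   sample_population(5, 5, synth_config(), seed = 3))
})

test_that("size calibration: a mean-diameter cell covers ~500 pixels", {
  p <- synth_config()
  r_px <- 11.5 / p$pixel_scale_um / 2
  area <- pi * r_px^2
  expect_lt(abs(area - 500) / 500, 0.2)
})

test_that("placement fails loudly when the frame cannot hold the request", {
  tiny <- synth_config(shape = c(80L, 80L))
  expect_error(sample_population(200, 0, tiny, seed = 1),
               class = "ctcscope_placement_error")
})

test_that("rendering an empty scene gives background-only channels", {
  p <- synth_config(n_debris = 0)
  pair <- render_pair(list(), p, seed = 1)
  expect_s3_class(pair, "field_pair")
  expect_equal(dim(pair$bright), p$shape)
  # no fluorescence blob: nothing beyond extreme-value range of the noise
  for (ch in list(pair$fluor_green, pair$fluor_red)) {
    expect_lt(max(ch), median(ch) + 5 * p$fluor_noise_sd + 2)
  }
})

test_that("fluorescence channel routing is class-pure", {
  p <- synth_config()
  wbc <- list(structure(list(class_label = "WBC", center_rc = c(240, 320),
                             diameter_um = 11.5, diameter_px = 25,
                             intensity_profile = p$profiles$WBC,
                             is_very_bright = FALSE), class = "synth_cell"))
  wbc[[1]]$intensity_profile$texture_seed <- 99
  pair <- render_pair(wbc, p, seed = 2)
  gmax <- which(pair$fluor_green == max(pair$fluor_green), arr.ind = TRUE)[1, ]
  expect_lt(sqrt((gmax[1] - 1 - 240)^2 + (gmax[2] - 1 - 320)^2), 2 + 1e-9)
  expect_lt(max(pair$fluor_red), median(pair$fluor_red) + 5 * p$fluor_noise_sd + 2)

  # property over a mixed population: above-background signal only in the
  # class channel at each center
  cells <- sample_population(20, 8, p, seed = 11)
  mix <- render_pair(cells, p, seed = 11)
  g_bg <- median(mix$fluor_green); r_bg <- median(mix$fluor_red)
  for (cell in cells) {
    at <- cbind(round(cell$center_rc[1]) + 1, round(cell$center_rc[2]) + 1)
    g <- mix$fluor_green[at] - g_bg; r <- mix$fluor_red[at] - r_bg
    if (cell$class_label == "WBC") {
      expect_gt(g, 50); expect_lt(r, 20)
    } else {
      expect_gt(r, 50); expect_lt(g, 20)
    }
  }
})

test_that("rendering is deterministic for fixed cells and seed", {
  p <- synth_config()
  cells <- sample_population(10, 2, p, seed = 4)
  a <- render_pair(cells, p, seed = 4)
  b <- render_pair(cells, p, seed = 4)
  expect_identical(a$bright, b$bright)
  expect_identical(a$fluor_red, b$fluor_red)
})

test_that("write_pair / read_pair round-trips bit- and field-exactly", {
  p <- synth_config()
  cells <- sample_population(6, 2, p, seed = 9)
  pair <- render_pair(cells, p, seed = 9)
  dir <- withr::local_tempdir()
  write_pair(pair, dir)

  df <- read.csv(file.path(dir, "cells.csv"))
  expect_equal(nrow(df), 8)
  expect_equal(names(df), c("class", "row", "col", "diameter_um"))

  back <- read_pair(dir)
  expect_identical(back$bright, pair$bright)
  expect_identical(back$fluor_green, pair$fluor_green)
  expect_identical(back$fluor_red, pair$fluor_red)
  expect_equal(back$cells, pair$cells, tolerance = 1e-12)
  expect_equal(back$pixel_scale_um, pair$pixel_scale_um)

  file.remove(file.path(dir, "fluor_red.png"))
  expect_error(read_pair(dir), "fluor_red", class = "ctcscope_io_error")
})
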