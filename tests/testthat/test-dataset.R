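fake_region <- function(r, c, area = 500, solidity = 0.97, ecc = 0.2,
                        half = 12) {
  structure(list(region_id = 1L, centroid_rc = c(r, c),
                 bbox = c(r - half, c - half, r + half, c + half),
                 area_px = area, solidity = solidity, eccentricity = ecc),
            class = "cell_region")
}

test_that("crop_cells centers, pads and preserves order", {
  img <- matrix(seq_len(200 * 200), 200, 200)
  regions <- list(fake_region(100, 100), fake_region(5, 5), fake_region(50, 60))
  crops <- crop_cells(img, regions, side = 30, frame_id = "f")
  expect_length(crops, 3)

  # centroid (100,100): rows/cols [85,115) 0-based
  expect_identical(crops[[1]]$pixels, img[86:115, 86:115])
  expect_equal(crops[[1]]$centroid_rc, c(100, 100))

  # near-border crop is edge-replicated to full size
  expect_equal(dim(crops[[2]]$pixels), c(30, 30))
  expect_identical(crops[[2]]$pixels[1, ], crops[[2]]$pixels[10, ])  # top rows replicate row 0

  expect_equal(vapply(crops, `[[`, "", "crop_id"),
               c("f_r001", "f_r002", "f_r003"))
})

test_that("labels transfer from the correct fluorescence channel", {
  fx <- seg_fixture()
  crops <- crop_cells(fx$pair$bright, fx$seg$regions, frame_id = "fx")
  labeled <- transfer_labels(crops, fx$pair$fluor_green, fx$pair$fluor_red)
  true_ctrs <- t(vapply(fx$cells, function(s) s$center_rc, numeric(2)))
  true_cls <- vapply(fx$cells, `[[`, "", "class_label")
  hits <- 0
  for (cr in labeled) {
    d <- sqrt((true_ctrs[, 1] - cr$centroid_rc[1])^2 +
              (true_ctrs[, 2] - cr$centroid_rc[2])^2)
    if (min(d) <= 3) {
      hits <- hits + 1
      expect_identical(cr$label, true_cls[which.min(d)])
    } else {
      expect_identical(cr$label, "UNLABELED")
    }
  }
  expect_gte(hits, 38)   # 40 cells in the fixture, >= 95% matched

  # background location stays unlabeled
  bg_crop <- crop_cells(fx$pair$bright, list(fake_region(240, 10)),
                        frame_id = "bg")
  bg_crop[[1]]$frame_shape <- dim(fx$pair$fluor_green)
  expect_identical(transfer_labels(bg_crop, fx$pair$fluor_green,
                                   fx$pair$fluor_red)[[1]]$label, "UNLABELED")

  expect_error(transfer_labels(crops, fx$pair$fluor_green[1:100, ],
                               fx$pair$fluor_red),
               class = "ctcscope_format_error")
})

test_that("quality_filter applies rules in order with named reasons", {
  img <- matrix(100, 200, 200) + matrix(rnorm(40000), 200)
  good <- fake_region(100, 100)
  small <- fake_region(60, 60, area = 40)
  ragged <- fake_region(140, 140, solidity = 0.5)
  edge <- fake_region(100, 5)
  regions <- list(good, small, ragged, edge)
  crops <- crop_cells(img, regions, frame_id = "q")
  qf <- quality_filter(crops, regions, quality_rules())
  expect_length(qf$kept, 1)
  expect_identical(qf$kept[[1]]$crop_id, "q_r001")
  reasons <- vapply(qf$rejected, `[[`, "", "reason")
  expect_identical(reasons, c("area", "solidity", "margin"))

  # 60% bbox overlap rejects both partners
  a <- fake_region(100, 100); b <- fake_region(100, 109.6)
  ov <- list(a, b)
  crops2 <- crop_cells(img, ov, frame_id = "o")
  qf2 <- quality_filter(crops2, ov, quality_rules(max_overlap = 0.3))
  expect_length(qf2$kept, 0)
  expect_identical(vapply(qf2$rejected, `[[`, "", "reason"),
                   c("overlap", "overlap"))
  # count conservation
  expect_equal(length(qf$kept) + length(qf$rejected), length(crops))
})

test_that("normalize_crop removes planes, standardizes, and is idempotent", {
  rr <- matrix(rep(0:29, 30), 30); cc <- t(rr)
  ramp <- 0.7 * rr + 0.3 * cc + 5
  # a pure plane is exactly captured by the border fit ...
  resid <- ramp - ctcscope:::fit_border_plane(ramp)
  expect_lt(max(abs(resid)), 1e-6)
  # ... leaving nothing to standardize
  crop_ramp <- ctcscope:::new_cell_crop("r", ramp, "t", c(0, 0))
  expect_error(normalize_crop(crop_ramp), class = "ctcscope_degenerate_error")

  crop_const <- ctcscope:::new_cell_crop("c", matrix(3, 30, 30), "t", c(0, 0))
  expect_error(normalize_crop(crop_const), class = "ctcscope_degenerate_error")

  fx <- seg_fixture()
  crops <- crop_cells(fx$pair$bright, fx$seg$regions, frame_id = "n")
  cr <- crops[[1]]
  n1 <- normalize_crop(cr)
  expect_lt(abs(mean(n1$pixels)), 1e-10)
  expect_equal(sd(n1$pixels), 1, tolerance = 1e-10)
  n2 <- normalize_crop(n1)
  expect_lt(max(abs(n2$pixels - n1$pixels)), 1e-6)

  # tilt invariance: adding a ramp changes the normalized result negligibly
  cr_ramp <- cr
  cr_ramp$pixels <- cr$pixels + ramp
  nr_ <- normalize_crop(cr_ramp)
  expect_lt(max(abs(nr_$pixels - n1$pixels)), 1e-3)
})

test_that("augmentation hits per-class targets with provenance intact", {
  toy <- make_toy_crops(5)
  ctc3 <- toy[6:8]; wbc5 <- toy[1:5]
  aug <- augment_crops(c(ctc3, wbc5), augment_spec(target_per_class = 10, seed = 2))
  labs <- vapply(aug, `[[`, "", "label")
  expect_equal(sum(labs == "CTC"), 10)
  expect_equal(sum(labs == "WBC"), 10)
  src_ids <- vapply(c(ctc3, wbc5), `[[`, "", "crop_id")
  expect_true(all(vapply(aug, `[[`, "", "origin_id") %in% src_ids))

  # the printed study size: 1000 per class
  aug1k <- augment_crops(toy, augment_spec(target_per_class = 1000, seed = 3))
  labs1k <- vapply(aug1k, `[[`, "", "label")
  expect_equal(sum(labs1k == "WBC"), 1000)
  expect_equal(sum(labs1k == "CTC"), 1000)

  # identity spec with target = source count is pixel-exact
  idspec <- augment_spec(target_per_class = 5, rotation_range_deg = 0,
                         shear_range = 0, allow_hflip = FALSE,
                         allow_vflip = FALSE, seed = 1)
  id_aug <- augment_crops(toy, idspec)
  expect_length(id_aug, 10)
  for (i in seq_along(id_aug))
    expect_identical(id_aug[[i]]$pixels, toy[[i]]$pixels)

  expect_error(augment_crops(wbc5, augment_spec(target_per_class = 4)),
               class = "ctcscope_class_coverage_error")

  # determinism
  expect_equal(augment_crops(toy, augment_spec(target_per_class = 20, seed = 5)),
               augment_crops(toy, augment_spec(target_per_class = 20, seed = 5)))
})

test_that("augmented transforms preserve class structure under rotation", {
  fx <- crops_fixture()
  aug <- augment_crops(fx, augment_spec(target_per_class = 60, seed = 7))
  new <- aug[vapply(aug, `[[`, "", "transform_desc") != "identity"]
  expect_gt(length(new), 0)
  for (cr in new[1:5]) {
    expect_equal(dim(cr$pixels), c(30, 30))
    expect_true(cr$origin_id %in% vapply(fx, `[[`, "", "crop_id"))
  }
})
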