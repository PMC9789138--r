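test_that("bright-pixel thresholding is inclusive and counts correctly", {
  img <- matrix(c(0.66, 0.64, 0.65, 0), 2, 2)
  out <- threshold_mask(img, 0.65)
  expect_identical(out, matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))

  expect_false(any(threshold_mask(matrix(0, 10, 10), 0.35)))

  # linear ramp: positive count equals the closed-form count of samples >= t
  ramp <- matrix(seq(0, 1, length.out = 101), 101, 1)
  expect_equal(sum(threshold_mask(ramp, 0.65)), sum(seq(0, 1, by = 0.01) >= 0.65))

  expect_error(threshold_mask(img, 1.5), "\\[0, 1\\]")
  expect_error(threshold_mask(img, -0.1), "\\[0, 1\\]")
})

test_that("seed-mask construction composes OR, hole fill, AND, area filter", {
  cfg <- segmentation_config()
  nr <- 40; nc <- 40
  empty <- matrix(FALSE, nr, nc)
  cellm <- matrix(TRUE, nr, nc)
  expect_identical(build_seed_mask(empty, empty, cellm, cfg), empty)

  # a bright ring enclosing a 945-px hole (< 1000), inside the cell mask:
  # the hole is filled and the region kept
  ring <- matrix(FALSE, 45, 45)
  ring[5:41, 5:33] <- TRUE
  ring[6:40, 6:32] <- FALSE   # 35 x 27 = 945 px hole
  big_cell <- matrix(TRUE, 45, 45)
  seeds <- build_seed_mask(ring, matrix(FALSE, 45, 45), big_cell, cfg)
  expect_true(all(seeds[6:40, 6:32]))   # hole (< 1000 px, 4-conn) was filled
  expect_true(all(seeds[ring]))

  # the same ring with the hole widened beyond 1000 px is not filled
  ring2 <- matrix(FALSE, 45, 45)
  ring2[4:42, 4:34] <- TRUE
  ring2[5:41, 5:33] <- FALSE  # 37 x 29 = 1073 px hole
  seeds2 <- build_seed_mask(ring2, matrix(FALSE, 45, 45), big_cell, cfg)
  expect_false(any(seeds2[5:41, 5:33]))

  # AND with the cell mask restricts seeds, area filter drops < 30 px
  blob <- matrix(FALSE, 40, 40); blob[10:14, 10:15] <- TRUE  # 30 px
  tiny <- matrix(FALSE, 40, 40); tiny[30:34, 30:35] <- TRUE; tiny[30, 35] <- FALSE # 29 px
  seeds3 <- build_seed_mask(blob | tiny, empty, cellm, cfg)
  expect_true(all(seeds3[10:14, 10:15]))
  expect_false(any(seeds3[30:34, 30:35]))
  no_cell <- build_seed_mask(blob, empty, empty, cfg)
  expect_false(any(no_cell))

  expect_error(build_seed_mask(empty, matrix(FALSE, 2, 2), cellm, cfg),
               "dimensions")
})

test_that("seeded growth dilates, clips to cells and reassigns small remainders", {
  cfg <- segmentation_config()
  d2 <- function(n, r0, c0) outer(seq_len(n) - r0, rep(1, n))^2 +
    outer(rep(1, n), seq_len(n) - c0)^2

  # no seeds: a large cell component stays attached
  cellm <- matrix(FALSE, 60, 60); cellm[5:50, 5:50] <- TRUE  # 2116 px
  det <- grow_detached_mask(matrix(FALSE, 60, 60), cellm, cfg)
  expect_false(any(det$mask))

  # a central seed in a radius-9 cell (253 px): ring remainder (172 px) stays
  cell_big <- d2(41, 21, 21) <= 81
  seed <- matrix(FALSE, 41, 41); seed[21, 21] <- TRUE
  det_big <- grow_detached_mask(seed, cell_big, cfg)
  expect_identical(det_big$mask, (d2(41, 21, 21) <= 25) & cell_big)

  # a central seed in a radius-6 cell (113 px): 32-px remainder is reassigned,
  # making the whole cell detached
  cell_small <- d2(41, 21, 21) <= 36
  det_small <- grow_detached_mask(seed, cell_small, cfg)
  expect_identical(det_small$mask, cell_small)

  # detached mask is always a subset of the cell mask
  set.seed(19)
  for (i in 1:10) {
    s <- random_mask(48, 48); cm <- random_mask(48, 48)
    out <- grow_detached_mask(s, cm, cfg)$mask
    expect_true(all(out <= cm))
  }
})

test_that("the percentage feature and its degenerate cases behave", {
  cm <- matrix(FALSE, 40, 40); cm[1:25, 1:40] <- TRUE  # 1000 px
  det <- matrix(FALSE, 40, 40); det[1:25, 1:10] <- TRUE  # 250 px
  expect_equal(percent_detached(det, cm), 25)
  expect_equal(percent_detached(cm, cm), 100)
  expect_equal(percent_detached(matrix(FALSE, 40, 40), cm), 0)
  expect_true(is.na(percent_detached(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4))))
  bad <- matrix(FALSE, 40, 40); bad[30, 30] <- TRUE
  expect_error(percent_detached(bad, cm), "invariant")
})

test_that("absolute error is symmetric and range-checked", {
  expect_equal(absolute_error(50, 50), 0)
  expect_equal(absolute_error(92.5, 90), 2.5)
  set.seed(3)
  a <- runif(100, 0, 100); b <- runif(100, 0, 100)
  expect_equal(absolute_error(a, b), absolute_error(b, a))
  expect_error(absolute_error(101, 50), "\\[0, 100\\]")
  expect_error(absolute_error(50, -1), "\\[0, 100\\]")
})

test_that("end-to-end extraction separates attached from detached scenes", {
  model <- cached_model()
  cfg <- segmentation_config()
  run <- function(fr) {
    cm <- postprocess_cell_mask(predict_cell_mask(model, fr$pair$phase),
                                cfg$cell_fill_hole_lt, cfg$cell_min_area)
    det <- extract_detached_regions(fr$pair, cm, cfg)
    list(cm = cm, det = det, pct = percent_detached(det, cm))
  }
  att <- run(render_static_frame(22, 0, canvas = 160, seed = 81))
  expect_lt(att$pct, 2)
  det <- run(render_static_frame(22, 1, canvas = 160, seed = 82))
  expect_gt(det$pct, 98)

  # partition: attached and detached tile the cell mask exactly
  mid <- run(render_static_frame(22, 0.5, canvas = 160, seed = 83))
  attached <- mid$cm$mask & !mid$det$mask
  expect_false(any(attached & mid$det$mask))
  expect_identical(attached | mid$det$mask, mid$cm$mask)

  # a frame with zero cell pixels yields a flagged (missing) percentage
  empty <- render_static_frame(0, 0, canvas = 96, seed = 84)
  cm0 <- postprocess_cell_mask(predict_cell_mask(model, empty$pair$phase),
                               cfg$cell_fill_hole_lt, cfg$cell_min_area)
  det0 <- extract_detached_regions(empty$pair, cm0, cfg)
  expect_true(is.na(percent_detached(det0, cm0)))

  # segmentation refuses un-normalized pairs
  raw_pair <- reconstructed_pair(matrix(0.5, 8, 8), matrix(0.5, 8, 8))
  expect_error(extract_detached_regions(raw_pair, cell_mask(matrix(TRUE, 8, 8))),
               "normalized")
})

test_that("lowering the intensity threshold never shrinks the seed mask", {
  model <- cached_model()
  fr <- render_static_frame(20, 0.5, canvas = 160, seed = 91)
  cm <- postprocess_cell_mask(predict_cell_mask(model, fr$pair$phase))
  pb <- threshold_mask(fr$pair$phase, 0.65)
  sizes <- vapply(c(0.6, 0.45, 0.35, 0.2), function(th) {
    ib <- threshold_mask(fr$pair$intensity, th)
    sum(build_seed_mask(pb, ib, cm))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})
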