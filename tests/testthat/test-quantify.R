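# Segmentation, per-cell measurement, positivity calls, kinetic slopes and
# round linking.

test_that("measure_cell matches hand computations", {
  img <- matrix(300, 4, 4)
  m <- measure_cell(matrix(TRUE, 4, 4), img, background = 50)
  expect_equal(unname(m["mean_fi"]), 250)
  expect_equal(unname(m["fi_sd"]), 0)

  img2 <- matrix(c(100, 200, 300), 3, 1)
  m2 <- measure_cell(matrix(TRUE, 3, 1), img2, background = 0)
  expect_equal(unname(m2["mean_fi"]), 200)
  expect_equal(unname(m2["fi_sd"]), sqrt(mean(c(-100, 0, 100)^2))) # 81.65
})

test_that("measure_cell rejects empty or out-of-image masks", {
  img <- matrix(0, 4, 4)
  expect_error(measure_cell(matrix(FALSE, 4, 4), img),
               class = "picocyte_parameter_error")
  expect_error(measure_cell(cbind(5, 1), img),
               class = "picocyte_parameter_error")
})

test_that("measure_cell is intensity-affine", {
  set.seed(3)
  img <- matrix(runif(64, 100, 400), 8, 8)
  mask <- matrix(rep(c(TRUE, FALSE), 32), 8, 8)
  a <- 2.5; bg <- 40
  m1 <- measure_cell(mask, img, background = bg)
  m2 <- measure_cell(mask, a * img, background = a * bg)
  expect_equal(unname(m2["mean_fi"]), a * unname(m1["mean_fi"]), tolerance = 1e-12)
  expect_equal(unname(m2["fi_sd"]), a * unname(m1["fi_sd"]), tolerance = 1e-12)
})

test_that("fit_slope recovers exact lines and handles degenerate input", {
  f <- fit_slope(list(t = 60 * (0:4), fi = c(10, 20, 30, 40, 50)))
  expect_equal(unname(f["slope"]), 10)
  expect_equal(unname(f["r2"]), 1)

  f0 <- fit_slope(list(t = 60 * (0:4), fi = rep(7, 5)))
  expect_equal(unname(f0["slope"]), 0)

  # baseline invariance
  f1 <- fit_slope(list(t = 60 * (0:4), fi = c(3, 9, 12, 14, 30)))
  f2 <- fit_slope(list(t = 60 * (0:4), fi = c(3, 9, 12, 14, 30) + 123))
  expect_equal(f1["slope"], f2["slope"])

  # n = 2 equals the closed-form two-point slope
  f3 <- fit_slope(list(t = c(0, 90), fi = c(5, 20)))
  expect_equal(unname(f3["slope"]), (20 - 5) / 1.5)

  expect_error(fit_slope(list(t = 0, fi = 5)),
               class = "picocyte_parameter_error")
  expect_error(fit_slope(list(t = c(0, 0), fi = c(1, 2))),
               class = "picocyte_parameter_error")
})

test_that("positivity calls use a strict threshold", {
  expect_equal(call_positive(c(99, 100, 101), 100), c(FALSE, FALSE, TRUE))
  expect_true(call_positive(126, list(k = 5), background_sd = 25))
  expect_false(call_positive(125, list(k = 5), background_sd = 25))
  expect_error(call_positive(1, list(k = 5)),
               class = "picocyte_config_error")
  expect_error(call_positive(1, list(bogus = TRUE)),
               class = "picocyte_config_error")
})

test_that("an empty field segments to an empty cell list", {
  sc <- tiny_scene(seed = 2)
  sc$cells <- sc$cells[0, ]
  img <- render_channel(sc, "transmitted", seed = 3)
  roi <- build_roi_map(sc$grid, sc$image_shape)
  seg <- segment_cells(img, roi)
  expect_equal(nrow(seg$cells), 0)
})

test_that("a saturated image raises a quality error", {
  sc <- tiny_scene(seed = 2)
  roi <- build_roi_map(sc$grid, sc$image_shape)
  img <- matrix(16383, sc$image_shape[1], sc$image_shape[2])
  expect_error(segment_cells(img, roi), class = "picocyte_quality_error")
})

test_that("two touching disks in one picowell are split by watershed", {
  sc <- tiny_scene(seed = 4, n_cells = 2, occupancy_mean = 2)
  # force both cells into one well, touching (centre distance ~1.7 r)
  s <- sc$grid$sites[1, ]
  r <- sc$cells$radius_px[1]
  sc$cells$picowell_id <- s$picowell_id
  sc$cells$i <- s$i; sc$cells$j <- s$j
  sc$cells$x <- s$x + c(-0.85 * r, 0.85 * r)
  sc$cells$y <- rep(s$y, 2)
  img <- render_channel(sc, "transmitted", seed = 5)
  roi <- build_roi_map(sc$grid, sc$image_shape)
  seg <- segment_cells(img, roi)
  expect_equal(nrow(seg$cells), 2)
  expect_equal(unique(seg$cells$picowell_id), s$picowell_id)
})

test_that("segmentation finds nearly all cells with accurate centroids", {
  sc <- sample_population(untreated_tmrm_population(), n_cells = 200,
                          occupancy_mean = 9.6, seed = 14)
  img <- render_channel(sc, "transmitted", seed = 15)
  roi <- build_roi_map(sc$grid, sc$image_shape)
  seg <- segment_cells(img, roi)
  expect_lt(abs(nrow(seg$cells) - nrow(sc$cells)) / nrow(sc$cells), 0.05)
  matched <- match_to_truth(seg$cells, sc, max_dist = 5)
  expect_gte(mean(!is.na(matched)), 0.95)
})

test_that("noise/PSF-free render-measure round trip is exact within 1 au", {
  # isolated cells, full masks: the rendered within-mask mean is realised
  # exactly, so segmentation + measurement must return it exactly
  sc <- sample_population(untreated_tmrm_population(), n_cells = 40,
                          occupancy_mean = 1, capacity = 1, seed = 24)
  timg <- render_channel(sc, "transmitted", noise = FALSE, psf = FALSE,
                         seed = 25)
  fimg <- render_channel(sc, "TMRM", noise = FALSE, psf = FALSE, seed = 26)
  roi <- build_roi_map(sc$grid, sc$image_shape)
  seg <- segment_cells(timg, roi, wall_band_px = 4) # no PSF tail to mask
  rec <- measure_cells(seg, fimg, background = sc$optics$fluor_background,
                       erode_px = 0)
  matched <- match_to_truth(rec, sc, max_dist = 3)
  ok <- !is.na(matched)
  expect_gte(mean(ok), 0.99)
  err <- abs(rec$mean_fi[matched[ok]] - sc$cells$true_tmrm_mean[ok])
  expect_gte(mean(err < 1), 0.99)
})

test_that("TMRM population statistics survive the full noisy round trip", {
  rt <- run_roundtrip_study(untreated_tmrm_population(), n_cells = 250,
                            channel = "TMRM", seed = 34)
  true_mean <- mean(rt$scene$cells$true_tmrm_mean)
  sem <- sd(rt$scene$cells$true_tmrm_mean) / sqrt(nrow(rt$records))
  expect_lt(abs(mean(rt$records$mean_fi) - true_mean), 3 * sem)
})

test_that("round linking is exact for identical rounds and robust to stage shift", {
  rec <- data.frame(picowell_id = rep(c("a", "b"), each = 3),
                    x = c(10, 30, 50, 110, 130, 150),
                    y = c(10, 30, 50, 10, 30, 50))
  reg0 <- data.frame(round = 1:2, field_id = "f1", x_um = 0, y_um = 0)
  lk <- link_rounds(rec, rec, reg0, microns_per_pixel = 1, max_dist_px = 5)
  expect_equal(nrow(lk$pairs), 6)
  expect_equal(lk$pairs$idx2[order(lk$pairs$idx1)], 1:6)
  expect_length(lk$unmatched1, 0)

  # round 2 translated by exactly the registry stage delta
  rec2 <- rec; rec2$x <- rec$x + 8; rec2$y <- rec$y - 4
  reg <- data.frame(round = 1:2, field_id = "f1",
                    x_um = c(0, 8), y_um = c(0, -4))
  lk2 <- link_rounds(rec, rec2, reg, microns_per_pixel = 1, max_dist_px = 5)
  expect_equal(lk2$pairs[order(lk2$pairs$idx1), c("idx1", "idx2")],
               lk$pairs[order(lk$pairs$idx1), c("idx1", "idx2")],
               ignore_attr = TRUE)

  expect_error(link_rounds(rec, rec, reg0, field_id = "nope"),
               class = "picocyte_parameter_error")
})

test_that("linking survives segmentation jitter at >= 98% accuracy", {
  sc <- sample_population(untreated_tmrm_population(), n_cells = 200,
                          occupancy_mean = 9.6, seed = 44)
  rounds <- render_rounds(sc, seed = 45)
  an <- analyze_rounds(rounds, 0.65)
  rec <- an$records[!an$records$edge, ]
  expect_gte(mean(rec$matched), 0.98)
  # matched pairs point at the same physical cell: compare to ground truth
  m1 <- match_to_truth(an$seg1$cells, sc, max_dist = 5)
  m2 <- match_to_truth(an$seg2$cells, rounds$scene2, max_dist = 5)
  pairs <- an$link$pairs
  truth1 <- match(pairs$idx1, m1)
  truth2 <- match(pairs$idx2, m2)
  ok <- !is.na(truth1) & !is.na(truth2)
  expect_gte(mean(truth1[ok] == truth2[ok]), 0.98)
})
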