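# Lattice detection, ROI tessellation and occupancy flags.

test_that("generator round trip recovers pitch and orientation at 100 um", {
  sc <- sample_population(untreated_tmrm_population(), n_picowells = 25,
                          occupancy_mean = 5, seed = 11)
  img <- render_channel(sc, "transmitted", seed = 12)
  g <- detect_lattice(img, 0.65)
  expect_lt(abs(g$pitch_px - sc$grid$pitch_px), 1)
  dth <- g$orientation %% (pi / 3) # circular distance to 0 mod 60 deg
  expect_lt(min(dth, pi / 3 - dth) * 180 / pi, 0.5)
  # origin lies on the true lattice (mod basis)
  duv <- solve(sc$grid$basis) %*% (g$origin - sc$grid$origin)
  expect_lt(max(abs(duv - round(duv))), 0.05)
})

test_that("a rotated grid is recovered modulo the hexagonal symmetry", {
  g0 <- picowell_grid(100, 0.65, 6, 6, orientation = 17 * pi / 180)
  sc <- sample_population(untreated_tmrm_population(), grid = g0,
                          n_picowells = 25, occupancy_mean = 5, seed = 21)
  img <- render_channel(sc, "transmitted", seed = 22)
  g <- detect_lattice(img, 0.65)
  dth <- (g$orientation - 17 * pi / 180) %% (pi / 3)
  dth <- min(dth, pi / 3 - dth) * 180 / pi
  expect_lt(dth, 0.5)
  expect_lt(abs(g$pitch_px - g0$pitch_px), 1)
})

test_that("the 20-um single-cell pitch is recovered within a pixel", {
  sc <- sample_population(untreated_tmrm_population(), pitch_um = 20,
                          n_picowells = 400, occupancy_mean = 0.8,
                          cell_radius_um = 4.5, seed = 31)
  img <- render_channel(sc, "transmitted", seed = 32)
  g <- detect_lattice(img, 0.65)
  expect_lt(abs(g$pitch_px - sc$grid$pitch_px), 1)
})

test_that("translating the image leaves pitch/orientation unchanged and shifts the origin", {
  sc <- sample_population(untreated_tmrm_population(), n_picowells = 25,
                          occupancy_mean = 5, seed = 41)
  img <- render_channel(sc, "transmitted", seed = 42)
  g1 <- detect_lattice(img, 0.65)
  v <- c(23, 11)
  img2 <- img
  img2[(v[1] + 1):nrow(img), (v[2] + 1):ncol(img)] <-
    img[1:(nrow(img) - v[1]), 1:(ncol(img) - v[2])]
  g2 <- detect_lattice(img2, 0.65)
  expect_lt(abs(g2$pitch_px - g1$pitch_px), 0.5)
  expect_lt(abs(g2$orientation - g1$orientation) * 180 / pi, 0.5)
  duv <- solve(g1$basis) %*% (g2$origin - (g1$origin + v))
  expect_lt(max(abs(duv - round(duv))), 0.1)
})

test_that("pure noise raises a detection error with a diagnostic", {
  set.seed(1)
  img <- matrix(rnorm(512 * 512, 1000, 50), 512, 512)
  expect_error(detect_lattice(img, 0.65),
               class = "picocyte_detection_error")
})

test_that("ROI map tessellates the lattice without overlap or gaps", {
  g <- picowell_grid(50 * 0.65, 0.65, 3, 3) # pitch 50 px
  roi <- build_roi_map(g, g$image_shape)
  expect_gte(sum(roi$sites$interior), 9)
  # every pixel has exactly one label by construction; labels cover image
  expect_true(all(roi$labels >= 0))
  expect_equal(sum(tabulate(roi$labels, nbins = nrow(roi$sites))) +
                 sum(roi$labels == 0), prod(g$image_shape))
})

test_that("interior ROI areas match the closed-form hexagon area within 2%", {
  g <- picowell_grid(50 * 0.65, 0.65, 5, 5)
  shape <- g$image_shape
  roi <- build_roi_map(g, shape)
  hex_area <- sqrt(3) / 2 * g$pitch_px^2
  interior <- roi$sites[roi$sites$interior, ]
  expect_gt(nrow(interior), 0)
  expect_true(all(abs(interior$area_px - hex_area) / hex_area < 0.02))
})

test_that("true cell centroids map to their ground-truth picowell", {
  sc <- sample_population(untreated_tmrm_population(), n_cells = 300,
                          occupancy_mean = 9.6, seed = 51)
  roi <- build_roi_map(sc$grid, sc$image_shape)
  cell_roi <- true_roi_of_cells(sc, roi)
  mapped_id <- roi$sites$picowell_id[cell_roi]
  expect_gte(mean(mapped_id == sc$cells$picowell_id), 0.99)
})

test_that("degenerate grids are rejected", {
  g <- picowell_grid(100, 0.65, 3, 3)
  g$pitch_px <- 1
  expect_error(build_roi_map(g, c(50, 50)),
               class = "picocyte_parameter_error")
})

test_that("occupancy flags match ground truth", {
  sc <- sample_population(untreated_tmrm_population(), n_picowells = 25,
                          occupancy_mean = 5, seed = 61)
  img <- render_channel(sc, "transmitted", seed = 62)
  roi <- build_roi_map(sc$grid, sc$image_shape)
  occ <- occupancy(roi, img)
  truth <- table(sc$cells$picowell_id)
  true_occ <- occ$picowell_id %in% names(truth)
  expect_gte(mean(occ$occupied == true_occ), 0.98)
})

test_that("an empty field has no occupied picowells and a single cell exactly one", {
  sc <- sample_population(untreated_tmrm_population(), n_picowells = 25,
                          occupancy_mean = 5, seed = 71)
  sc$cells <- sc$cells[0, ]
  img <- render_channel(sc, "transmitted", seed = 72)
  roi <- build_roi_map(sc$grid, sc$image_shape)
  expect_equal(sum(occupancy(roi, img)$occupied), 0)

  sc1 <- sample_population(untreated_tmrm_population(), n_picowells = 25,
                           occupancy_mean = 5, seed = 73)
  sc1$cells <- sc1$cells[1, , drop = FALSE]
  img1 <- render_channel(sc1, "transmitted", seed = 74)
  expect_equal(sum(occupancy(roi, img1)$occupied), 1)
})

test_that("doubling the read noise changes the recovered pitch by < 1%", {
  sc <- sample_population(untreated_tmrm_population(), n_picowells = 25,
                          occupancy_mean = 5, seed = 81)
  img1 <- render_channel(sc, "transmitted", seed = 82)
  sc2 <- sc
  sc2$optics$read_sd <- 2 * sc$optics$read_sd
  img2 <- render_channel(sc2, "transmitted", seed = 82)
  p1 <- detect_lattice(img1, 0.65)$pitch_px
  p2 <- detect_lattice(img2, 0.65)$pitch_px
  expect_lt(abs(p2 - p1) / p1, 0.01)
})
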