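# The synthetic field generator: population sampling, forward imaging
# model, kinetics and growth.

test_that("degenerate one-subgroup mixture assigns every cell to it", {
  sc <- tiny_scene(seed = 2)
  expect_true(all(sc$cells$subgroup == "live"))
})

test_that("invalid mixtures and occupancies are rejected", {
  expect_error(subgroup_params("a", 0.5, 100, 10, 50, 5, 10, 2, FALSE, FALSE),
               class = "picocyte_parameter_error")
  expect_error(sample_population(untreated_tmrm_population(),
                                 n_cells = 10, occupancy_mean = 30, seed = 1),
               class = "picocyte_parameter_error")
  expect_error(sample_population(untreated_tmrm_population(), seed = 1),
               class = "picocyte_parameter_error")
})

test_that("post-thaw mixture fractions are recovered within binomial bounds", {
  params <- postthaw_subgroups()
  sc <- sample_population(params, n_cells = 1000, occupancy_mean = 9.6,
                          seed = 42)
  counts <- table(factor(sc$cells$subgroup, levels = params$name))
  for (k in seq_len(nrow(params))) {
    lo <- qbinom(0.005, 1000, params$fraction[k])
    hi <- qbinom(0.995, 1000, params$fraction[k])
    expect_gte(counts[[params$name[k]]], lo)
    expect_lte(counts[[params$name[k]]], hi)
  }
})

test_that("occupancy follows the capacity-truncated Poisson", {
  # oracle: mean of the truncated pmf by direct enumeration over 0..20
  lambda <- 9.6; cap <- 20
  pmf <- dpois(0:cap, lambda)
  mu <- sum((0:cap) * pmf) / sum(pmf)
  sdv <- sqrt(sum((0:cap)^2 * pmf) / sum(pmf) - mu^2)
  sc <- sample_population(untreated_tmrm_population(), n_picowells = 200,
                          occupancy_mean = lambda, seed = 7)
  cnt <- tabulate(factor(sc$cells$picowell_id,
                         levels = sc$grid$sites$picowell_id[1:200]),
                  nbins = 200)
  expect_lt(abs(mean(cnt) - mu), 3 * sdv / sqrt(200))
})

test_that("scenes and renders are bit-identical for identical seeds", {
  s1 <- tiny_scene(seed = 9); s2 <- tiny_scene(seed = 9)
  expect_identical(s1$cells, s2$cells)
  i1 <- render_channel(s1, "TMRM", seed = 3)
  i2 <- render_channel(s2, "TMRM", seed = 3)
  expect_identical(i1, i2)
  k1 <- render_kinetic_series(s1, seed = 4)
  k2 <- render_kinetic_series(s2, seed = 4)
  expect_identical(k1, k2)
})

test_that("cells never overlap more than the configured fraction", {
  sc <- sample_population(untreated_tmrm_population(), n_picowells = 8,
                          occupancy_mean = 12, seed = 13, max_overlap = 0.1)
  r <- sc$cells$radius_px[1]
  dmin <- picocyte:::min_centre_distance(r, 0.1)
  for (w in unique(sc$cells$picowell_id)) {
    cc <- sc$cells[sc$cells$picowell_id == w, ]
    if (nrow(cc) < 2) next
    d <- as.matrix(dist(cc[, c("x", "y")]))
    expect_gte(min(d[upper.tri(d)]), dmin - 1e-9)
  }
})

test_that("empty scene renders a uniform fluorescence background", {
  sc <- tiny_scene(seed = 1)
  sc$cells <- sc$cells[0, ]
  img <- render_channel(sc, "TMRM", noise = FALSE, psf = FALSE)
  expect_equal(length(unique(as.vector(img))), 1)
  expect_equal(img[1, 1], sc$optics$fluor_background)
})

test_that("noise/PSF-free forward model realises the true mask mean exactly", {
  sc <- tiny_scene(seed = 5, n_cells = 1, occupancy_mean = 1)
  sc$cells$true_tmrm_mean <- 500
  sc$cells$true_tmrm_sd <- 150
  img <- render_channel(sc, "TMRM", noise = FALSE, psf = FALSE)
  x <- sc$cells$x; y <- sc$cells$y; r <- sc$cells$radius_px
  mask <- which(outer(seq_len(nrow(img)) - x, seq_len(ncol(img)) - y,
                      function(a, b) a^2 + b^2) <= r^2, arr.ind = TRUE)
  m <- measure_cell(mask, img, background = sc$optics$fluor_background)
  expect_lt(abs(m["mean_fi"] - 500), 1)
  expect_lt(abs(m["fi_sd"] - 150), 1)
})

test_that("number of rendered disks matches the cell list in every channel", {
  sc <- tiny_scene(seed = 6, n_cells = 12, occupancy_mean = 1,
                   params = postthaw_subgroups(), capacity = 1)
  # count connected bright components in a noise-free PI render of PI+ cells
  img <- render_channel(sc, "FITC", noise = FALSE, psf = FALSE)
  lab <- EBImage::bwlabel(img > sc$optics$fluor_background + 1)
  expect_equal(max(lab), nrow(sc$cells))
})

test_that("kinetic series follows the linear forward model", {
  sc <- tiny_scene(seed = 8, n_cells = 3, occupancy_mean = 1)
  sc$optics$fda_baseline <- 0
  sc$cells$true_fda_slope <- 10
  fr <- render_kinetic_series(sc, noise = FALSE, psf = FALSE)
  expect_equal(vapply(fr, function(f) f$t, 0), 60 * (0:4))
  for (k in 1:5) {
    fg <- fr[[k]]$image > sc$optics$fluor_background + 0.5
    lvl <- if (any(fg))
      mean(fr[[k]]$image[fg]) - sc$optics$fluor_background else 0
    expect_lt(abs(lvl - 10 * (k - 1)), 1.5)
  }
})

test_that("zero slopes give frames identical up to texture redraw", {
  sc <- tiny_scene(seed = 8, n_cells = 3, occupancy_mean = 1)
  sc$cells$true_fda_slope <- 0
  fr <- render_kinetic_series(sc, noise = FALSE, psf = FALSE)
  fg <- fr[[1]]$image > sc$optics$fluor_background + 0.5
  means <- vapply(fr, function(f) mean(f$image[fg]), 0)
  expect_lt(diff(range(means)), 0.5)
})

test_that("PI-positive cells accumulate no fluorescein", {
  sc <- tiny_scene(seed = 8, n_cells = 2, occupancy_mean = 1)
  sc$cells$true_pi <- TRUE
  sc$cells$true_fda_slope <- 50
  sc$optics$fda_baseline <- 20
  fr <- render_kinetic_series(sc, noise = FALSE, psf = FALSE)
  # slope forced <= 0: frame 5 shows no mean increase over frame 1
  fg <- fr[[1]]$image > sc$optics$fluor_background + 0.5
  expect_lte(mean(fr[[5]]$image[fg]), mean(fr[[1]]$image[fg]) + 0.5)
})

test_that("kinetic parameter errors are raised", {
  sc <- tiny_scene(seed = 8, n_cells = 2, occupancy_mean = 1)
  expect_error(render_kinetic_series(sc, n_frames = 1),
               class = "picocyte_parameter_error")
  expect_error(render_kinetic_series(sc, dt = 0),
               class = "picocyte_parameter_error")
})

test_that("growth at ratio 1 +/- 0 leaves counts unchanged; doubling doubles", {
  sc <- sample_population(untreated_tmrm_population(), n_picowells = 10,
                          occupancy_mean = 5, seed = 3)
  g1 <- simulate_growth(sc, 1, 0, seed = 4)
  expect_equal(table(g1$cells$picowell_id), table(sc$cells$picowell_id))
  g2 <- simulate_growth(sc, 2, 0, seed = 4)
  t0 <- table(sc$cells$picowell_id)
  t48 <- table(g2$cells$picowell_id)[names(t0)]
  expect_equal(as.integer(t48), pmin(2 * as.integer(t0), sc$capacity))
})

test_that("growth respects capacity and keeps colonies in their picowell", {
  sc <- sample_population(untreated_tmrm_population(), n_picowells = 20,
                          occupancy_mean = 15, seed = 5)
  g <- simulate_growth(sc, 3, 0.5, seed = 6)
  cnt <- table(g$cells$picowell_id)
  expect_true(all(cnt <= sc$capacity))
  expect_true(all(unique(g$cells$picowell_id) %in%
                  unique(sc$cells$picowell_id)))
})

test_that("empirical mixture fractions pass a chi-squared fit at n = 10000", {
  params <- postthaw_subgroups()
  sc <- sample_population(params, n_cells = 10000, occupancy_mean = 9.6,
                          seed = 77)
  counts <- table(factor(sc$cells$subgroup, levels = params$name))
  p <- chisq.test(as.integer(counts), p = params$fraction)$p.value
  expect_gt(p, 0.01)
})
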