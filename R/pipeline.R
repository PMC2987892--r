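## End-to-end analysis of a two-round multi-parametric acquisition:
## lattice detection -> ROI tessellation -> per-round segmentation and
## measurement -> stage-registered round linking -> one merged cell table.

translate_grid <- function(grid, dx, dy) {
  grid$origin <- grid$origin + c(dx, dy)
  grid$sites$x <- grid$sites$x + dx
  grid$sites$y <- grid$sites$y + dy
  grid
}

#' Analyze a two-round picowell acquisition
#'
#' Detects the lattice on the round-1 transmitted image, tessellates ROIs,
#' segments and measures both rounds (round 1: TMRM mean FI / FI SD and
#' Annexin V positivity; round 2: PI positivity and the FDA kinetic slope),
#' links the rounds through the stage registry and returns one cell table.
#' Cells unmatched across rounds or in edge picowells are flagged, not
#' dropped.
#'
#' @param rounds list as produced by [render_rounds()] (or assembled from
#'   read images with the same structure)
#' @param microns_per_pixel image scale
#' @param registry stage-position table; defaults to `rounds$registry`
#' @param positive_k positivity thresholds for Annexin/PI, in background SDs
#' @param grid optional known [picowell_grid()], bypassing detection
#'   (low-contrast fallback)
#' @param ... segmentation options passed to [segment_cells()]
#' @return list: `records` (merged cell table), `grid`, `roi_map`,
#'   `seg1`, `seg2`, `link`
#' @export
analyze_rounds <- function(rounds, microns_per_pixel,
                           registry = rounds$registry, positive_k = 5,
                           grid = NULL, ...) {
  r1img <- rounds$round1$transmitted
  if (is.null(grid)) grid <- detect_lattice(r1img, microns_per_pixel)
  roi1 <- build_roi_map(grid, dim(r1img))
  seg1 <- segment_cells(r1img, roi1, rounds$round1$tmrm, ...)
  tmrm <- measure_cells(seg1, rounds$round1$tmrm)
  fitc <- measure_cells(seg1, rounds$round1$fitc)
  rec1 <- seg1$cells
  rec1$tmrm_mean_fi <- tmrm$mean_fi
  rec1$tmrm_fi_sd <- tmrm$fi_sd
  rec1$tmrm_background_sd <- attr(tmrm, "background_sd")
  rec1$annexin_positive <- call_positive(fitc$mean_fi, list(k = positive_k),
                                         attr(fitc, "background_sd"))

  fid <- registry$field_id[1]
  p1 <- registry[registry$round == 1 & registry$field_id == fid, ]
  p2 <- registry[registry$round == 2 & registry$field_id == fid, ]
  if (nrow(p1) != 1 || nrow(p2) != 1)
    param_error(sprintf("field '%s' missing from the stage registry", fid))
  dx <- (p2$x_um - p1$x_um) / microns_per_pixel
  dy <- (p2$y_um - p1$y_um) / microns_per_pixel
  roi2 <- build_roi_map(translate_grid(grid, dx, dy),
                        dim(rounds$round2$transmitted))
  seg2 <- segment_cells(rounds$round2$transmitted, roi2, rounds$round2$pi, ...)
  pim <- measure_cells(seg2, rounds$round2$pi)
  rec2 <- extract_traces(seg2, rounds$round2$fda)
  rec2$pi_positive <- call_positive(pim$mean_fi, list(k = positive_k),
                                    attr(pim, "background_sd"))

  lnk <- link_rounds(rec1, rec2, registry, microns_per_pixel)
  rec <- rec1
  rec$field_id <- fid
  rec$pi_positive <- NA
  rec$fda_slope <- NA_real_
  rec$fda_slope_r2 <- NA_real_
  rec$matched <- FALSE
  if (nrow(lnk$pairs)) {
    rec$pi_positive[lnk$pairs$idx1] <- rec2$pi_positive[lnk$pairs$idx2]
    rec$fda_slope[lnk$pairs$idx1] <- rec2$fda_slope[lnk$pairs$idx2]
    rec$fda_slope_r2[lnk$pairs$idx1] <- rec2$fda_slope_r2[lnk$pairs$idx2]
    rec$matched[lnk$pairs$idx1] <- TRUE
  }
  list(records = rec, grid = grid, roi_map = roi1,
       seg1 = seg1, seg2 = seg2, link = lnk)
}

#' Gate an analyzed cell table
#'
#' Restricts to analyzable cells (matched across rounds, interior
#' picowells), computes the population-relative thresholds, classifies, and
#' summarizes.
#'
#' @param records `analyze_rounds()` cell table
#' @param tmrm_low_cut,tmrm_negative_cut see [compute_thresholds()]
#' @return list: `records` (classified, analyzable subset), `excluded`
#'   (edge/unmatched rows), `thresholds`, `summary`
#' @export
classify_population <- function(records, tmrm_low_cut = 200,
                                tmrm_negative_cut = NULL) {
  keep <- records$matched & !records$edge
  analyzed <- records[keep, , drop = FALSE]
  if (nrow(analyzed) == 0) param_error("no analyzable cells")
  thr <- compute_thresholds(
    analyzed, tmrm_low_cut = tmrm_low_cut,
    tmrm_negative_cut = tmrm_negative_cut,
    background_sd = analyzed$tmrm_background_sd[1])
  analyzed <- classify_cells(analyzed, thr)
  list(records = analyzed, excluded = records[!keep, , drop = FALSE],
       thresholds = thr, summary = summarize_population(analyzed))
}

#' Simulate, image and analyze one multi-parametric field
#'
#' Convenience wrapper chaining [sample_population()], [render_rounds()],
#' [analyze_rounds()] and [classify_population()] with sub-seeds derived
#' from one master seed.
#'
#' @param params a [subgroup_params()] mixture
#' @param n_cells population size
#' @param seed master seed
#' @param occupancy_mean mean cells/picowell
#' @param microns_per_pixel,pitch_um geometry
#' @param ... passed to [sample_population()]
#' @return list: `scene`, `rounds`, `analysis`, `classified`
#' @export
run_multiparametric_study <- function(params, n_cells = 1000, seed = 1,
                                      occupancy_mean = 9.6,
                                      microns_per_pixel = 0.65,
                                      pitch_um = 100, ...) {
  scene <- sample_population(params, n_cells = n_cells,
                             occupancy_mean = occupancy_mean, seed = seed,
                             pitch_um = pitch_um,
                             microns_per_pixel = microns_per_pixel, ...)
  rounds <- render_rounds(scene, seed = seed + 1L)
  analysis <- analyze_rounds(rounds, microns_per_pixel)
  classified <- classify_population(analysis$records)
  list(scene = scene, rounds = rounds, analysis = analysis,
       classified = classified)
}

#' Simulate and count a proliferation experiment
#'
#' Generates a fully occupied picowell field at time 0, simulates 48-h
#' growth, renders both transmitted-light images, re-detects the lattice,
#' segments, counts per picowell at both timepoints and computes the growth
#' statistics.
#'
#' @param n_picowells number of picowells
#' @param occupancy_mean mean cells/picowell at time 0
#' @param ratio_mean,ratio_sd growth-ratio distribution
#' @param seed master seed
#' @param params population mixture for the rendered cells
#' @param microns_per_pixel,pitch_um geometry
#' @return list: `scene_t0`, `scene_t48`, `counts_t0`, `counts_t48`
#'   (analysis-side, with ROI sites), `growth`, `subsets`,
#'   `mean_count_t0` (mean over occupied picowells)
#' @export
run_proliferation_study <- function(n_picowells = 300, occupancy_mean = 9.6,
                                    ratio_mean = 1.26, ratio_sd = 0.71,
                                    seed = 1,
                                    params = untreated_tmrm_population(),
                                    microns_per_pixel = 0.65,
                                    pitch_um = 100) {
  scene0 <- sample_population(params, n_picowells = n_picowells,
                              occupancy_mean = occupancy_mean, seed = seed,
                              pitch_um = pitch_um,
                              microns_per_pixel = microns_per_pixel)
  scene48 <- simulate_growth(scene0, ratio_mean, ratio_sd, seed = seed + 1L)
  count_timepoint <- function(scene, rseed, grid = NULL) {
    img <- render_channel(scene, "transmitted", seed = rseed)
    if (is.null(grid)) grid <- detect_lattice(img, microns_per_pixel)
    roi <- build_roi_map(grid, dim(img))
    seg <- segment_cells(img, roi)
    list(counts = count_per_picowell(seg$cells, roi$sites), grid = grid)
  }
  t0 <- count_timepoint(scene0, seed + 2L)
  t48 <- count_timepoint(scene48, seed + 3L, grid = t0$grid)
  growth <- growth_ratios(t0$counts, t48$counts)
  occ0 <- t0$counts$count[t0$counts$count > 0]
  list(scene_t0 = scene0, scene_t48 = scene48,
       counts_t0 = t0$counts, counts_t48 = t48$counts,
       growth = growth, subsets = select_proliferating(growth),
       mean_count_t0 = mean(occ0))
}

#' Render-segment-measure round trip for one fluorescence channel
#'
#' Generates a field, renders the transmitted and requested fluorescence
#' channel with default PSF/noise, detects the lattice, segments and
#' measures every cell; for `channel = "FDA"` renders the timed series and
#' fits per-cell slopes instead.
#'
#' @param params population mixture
#' @param n_cells population size
#' @param channel `"TMRM"` or `"FDA"`
#' @param seed master seed
#' @param occupancy_mean,microns_per_pixel,pitch_um geometry
#' @return list: `scene`, `records` (measured cells, interior only)
#' @export
run_roundtrip_study <- function(params, n_cells = 1000,
                                channel = c("TMRM", "FDA"), seed = 1,
                                occupancy_mean = 9.6,
                                microns_per_pixel = 0.65, pitch_um = 100) {
  channel <- match.arg(channel)
  scene <- sample_population(params, n_cells = n_cells,
                             occupancy_mean = occupancy_mean, seed = seed,
                             pitch_um = pitch_um,
                             microns_per_pixel = microns_per_pixel)
  timg <- render_channel(scene, "transmitted", seed = seed + 1L)
  grid <- detect_lattice(timg, microns_per_pixel)
  roi <- build_roi_map(grid, dim(timg))
  seg <- segment_cells(timg, roi)
  rec <- if (channel == "TMRM") {
    img <- render_channel(scene, "TMRM", seed = seed + 2L)
    measure_cells(seg, img)
  } else {
    frames <- render_kinetic_series(scene, seed = seed + 2L)
    extract_traces(seg, frames)
  }
  list(scene = scene, records = rec[!rec$edge, , drop = FALSE])
}
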