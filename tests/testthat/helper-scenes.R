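# Shared fixtures: everything is generated in code at test time.

# Small, fast scene: a handful of cells at moderate occupancy.
tiny_scene <- function(seed = 1, n_cells = 20, occupancy_mean = 4,
                       params = untreated_tmrm_population(), ...) {
  sample_population(params, n_cells = n_cells,
                    occupancy_mean = occupancy_mean, seed = seed, ...)
}

# Map each ground-truth cell of a scene to the ROI id its true centroid
# falls in, for comparing against segmentation-side assignments.
true_roi_of_cells <- function(scene, roi_map) {
  idx <- cbind(pmin(pmax(round(scene$cells$x), 1), roi_map$image_shape[1]),
               pmin(pmax(round(scene$cells$y), 1), roi_map$image_shape[2]))
  roi_map$labels[idx]
}

# Match segmented cells to ground-truth cells by nearest centroid; returns
# per-true-cell the index of the matched segmented cell (NA if none within
# max_dist).
match_to_truth <- function(seg_cells, scene, max_dist = 5) {
  vapply(seq_len(nrow(scene$cells)), function(k) {
    d <- sqrt((seg_cells$x - scene$cells$x[k])^2 +
              (seg_cells$y - scene$cells$y[k])^2)
    if (length(d) == 0 || min(d) > max_dist) NA_integer_ else which.min(d)
  }, integer(1))
}

# Independent truth-table oracle for the gating logic: a literal
# transcription of the gate definitions, evaluated row by row.
oracle_classify <- function(df, thr) {
  vapply(seq_len(nrow(df)), function(k) {
    a <- df$annexin_positive[k]; p <- df$pi_positive[k]
    tm <- df$tmrm_mean_fi[k]; sl <- df$fda_slope[k]
    if (any(is.na(c(a, p, tm, sl)))) return("unclassifiable")
    if (!a && !p) return("live")
    if (a && p) return("late_apoptotic")
    if (!a && p) return("necrotic_unclassified")
    if (tm < thr$tmrm_negative_cut) "early_apoptotic_MMP_neg"
    else "early_apoptotic_MMP_pos"
  }, character(1))
}
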