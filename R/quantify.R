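## Per-cell segmentation and measurement.
##
## Segmentation runs on the transmitted-light image (every cell is visible
## there regardless of staining status): threshold the darkness against the
## robust background, remove the thin wall lattice by morphological opening,
## and split touching cells by watershed on the distance map.  Fluorescence
## statistics are computed per watershed label with a small mask erosion so
## PSF-blurred edge pixels do not bias the mean.

#' Segment cells within picowell ROIs
#'
#' @param transmitted_image transmitted-light matrix (cells darker than
#'   background)
#' @param roi_map a [build_roi_map()] for the same field
#' @param fluorescence_image optional fluorescence frame, only used for the
#'   saturation quality check
#' @param min_area_px discard components smaller than this
#' @param k_sd darkness threshold in robust background SDs
#' @param wall_band_px total width of the lattice-boundary band masked out
#'   of the foreground (the wall plus a margin for its PSF tail); the band
#'   is computed analytically from the ROI map's lattice, so cell masks are
#'   not eroded the way a morphological opening would
#' @param open_radius optional opening radius (px) applied after wall
#'   masking; 0 (default) disables it
#' @param ws_tolerance watershed tolerance on the distance map
#' @return object of class `cell_segmentation`: list with `labels` (integer
#'   matrix, 0 = background) and `cells` (data.frame: `cell_id`, `roi`,
#'   `picowell_id`, `x`, `y`, `area_px`, `edge`)
#' @export
segment_cells <- function(transmitted_image, roi_map,
                          fluorescence_image = NULL,
                          min_area_px = 50, k_sd = 5, wall_band_px = 10,
                          open_radius = 0, ws_tolerance = 1) {
  img <- transmitted_image
  if (!all(dim(img) == roi_map$image_shape))
    param_error("image and roi_map shapes differ")
  for (im in list(img, fluorescence_image)) {
    if (!is.null(im) && mean(im >= 16383) > 0.5)
      quality_error("saturated image: > 50% of pixels at full scale")
  }
  bg <- stats::median(img)
  s <- stats::mad(img)
  if (s == 0) s <- 1
  binary <- img < bg - k_sd * s
  binary <- binary & !(roi_map$wall_gap < wall_band_px)
  if (!any(binary))
    return(empty_segmentation(roi_map))
  opened <- binary
  if (open_radius > 0) {
    brush <- EBImage::makeBrush(2 * open_radius + 1, shape = "disc")
    opened <- EBImage::opening(binary, brush) > 0
  }
  if (!any(opened))
    return(empty_segmentation(roi_map))
  dm <- EBImage::distmap(opened)
  labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = ws_tolerance))
  labels <- matrix(as.integer(labels), nrow(img), ncol(img))
  segmentation_from_labels(labels, roi_map, min_area_px)
}

empty_segmentation <- function(roi_map) {
  structure(list(labels = matrix(0L, roi_map$image_shape[1],
                                 roi_map$image_shape[2]),
                 cells = data.frame(cell_id = character(0), roi = integer(0),
                                    picowell_id = character(0),
                                    x = numeric(0), y = numeric(0),
                                    area_px = numeric(0),
                                    edge = logical(0),
                                    stringsAsFactors = FALSE)),
            class = "cell_segmentation")
}

segmentation_from_labels <- function(labels, roi_map, min_area_px) {
  n <- max(labels)
  if (n == 0) return(empty_segmentation(roi_map))
  area <- tabulate(labels, nbins = n)
  keep <- which(area >= min_area_px)
  if (length(keep) == 0) return(empty_segmentation(roi_map))
  relab <- integer(n)
  relab[keep] <- seq_along(keep)
  pos <- labels > 0
  labels[pos] <- relab[labels[pos]]

  idx <- which(labels > 0)
  lab <- labels[idx]
  nx <- nrow(labels)
  ix <- ((idx - 1) %% nx) + 1
  iy <- ((idx - 1) %/% nx) + 1
  npx <- tabulate(lab, nbins = length(keep))
  cx <- rowsum(ix, lab)[, 1] / npx
  cy <- rowsum(iy, lab)[, 1] / npx
  roi <- roi_map$labels[cbind(pmin(pmax(round(cx), 1), nx),
                              pmin(pmax(round(cy), 1), ncol(labels)))]
  interior <- roi > 0 & roi_map$sites$interior[pmax(roi, 1)]
  cells <- data.frame(
    cell_id = sprintf("s%05d", seq_along(keep)),
    roi = roi,
    picowell_id = ifelse(roi > 0, roi_map$sites$picowell_id[pmax(roi, 1)],
                         NA_character_),
    x = cx, y = cy, area_px = npx, edge = !interior,
    stringsAsFactors = FALSE)
  structure(list(labels = labels, cells = cells),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("cell_segmentation: %d cells (%d at field edge)\n",
              nrow(x$cells), sum(x$cells$edge)))
  invisible(x)
}

#' Mean and dispersion of a cell's fluorescence
#'
#' `mean_fi` is the mean background-subtracted pixel value over the mask,
#' floored at 0; `fi_sd` the population SD over the same pixels.
#'
#' @param mask logical matrix (the cell's pixel set) or a 2-column index
#'   matrix
#' @param image fluorescence matrix
#' @param background scalar background level (au) subtracted pixel-wise
#' @return named numeric `c(mean_fi, fi_sd)`
#' @examples
#' img <- matrix(c(100, 200, 300), 3, 1)
#' measure_cell(matrix(TRUE, 3, 1), img, background = 0)
#' @export
measure_cell <- function(mask, image, background = 0) {
  v <- if (is.logical(mask)) {
    if (!all(dim(mask) == dim(image)))
      param_error("mask and image shapes differ")
    image[mask]
  } else {
    if (any(mask[, 1] < 1 | mask[, 1] > nrow(image) |
            mask[, 2] < 1 | mask[, 2] > ncol(image)))
      param_error("mask indices outside the image")
    image[mask]
  }
  if (length(v) == 0) param_error("empty mask")
  v <- v - background
  c(mean_fi = max(mean(v), 0), fi_sd = pop_sd(v))
}

# Background level and robust SD from non-cell pixels (cell masks dilated by
# `guard_px` are excluded so PSF halos do not contaminate the estimate).
estimate_background <- function(image, labels, guard_px = 4) {
  fg <- labels > 0
  if (any(fg)) {
    brush <- EBImage::makeBrush(2 * guard_px + 1, shape = "disc")
    fg <- EBImage::dilate(fg, brush) > 0
  }
  v <- image[!fg]
  if (length(v) < 100) v <- as.vector(image)
  c(level = stats::median(v), sd = stats::mad(v))
}

#' Per-cell intensity statistics over a whole segmentation
#'
#' Applies [measure_cell()] logic label-wise.  Masks are eroded by
#' `erode_px` before measuring (falling back to the full mask when fewer
#' than `min_px` pixels survive) so that edge pixels attenuated by the PSF
#' do not bias the mean; watershed boundaries between touching cells are
#' treated as mask edges.
#'
#' @param seg a [segment_cells()] result
#' @param image fluorescence matrix
#' @param background scalar background (au); default estimated as the median
#'   of non-cell pixels
#' @param erode_px mask erosion depth in px
#' @param min_px minimum eroded-mask size before falling back
#' @return `seg$cells` with `mean_fi`, `fi_sd`, plus attributes
#'   `background`, `background_sd`
#' @export
measure_cells <- function(seg, image, background = NULL, erode_px = 3,
                          min_px = 9) {
  labels <- seg$labels
  if (!all(dim(image) == dim(labels)))
    param_error("image and segmentation shapes differ")
  bgest <- estimate_background(image, labels)
  if (is.null(background)) background <- unname(bgest["level"])
  n <- nrow(seg$cells)
  out <- seg$cells
  if (n == 0) {
    out$mean_fi <- numeric(0); out$mean_fi_signed <- numeric(0)
    out$fi_sd <- numeric(0)
    attr(out, "background") <- unname(background)
    attr(out, "background_sd") <- unname(bgest["sd"])
    return(out)
  }
  core <- eroded_mask(labels, erode_px)
  stats_full <- label_stats(labels, image, labels > 0)
  stats_core <- label_stats(labels, image, core)
  use_core <- stats_core$n >= min_px
  m <- ifelse(use_core, stats_core$mean, stats_full$mean)
  s <- ifelse(use_core, stats_core$sd, stats_full$sd)
  out$mean_fi <- pmax(m - background, 0)
  out$mean_fi_signed <- m - background # unfloored, for kinetic fits
  out$fi_sd <- s
  attr(out, "background") <- unname(background)
  attr(out, "background_sd") <- unname(bgest["sd"])
  out
}

# Label-wise mean / population SD of image over pixels where sel is TRUE.
label_stats <- function(labels, image, sel) {
  nlab <- max(labels)
  lab <- labels[sel]
  v <- image[sel]
  n <- tabulate(lab, nbins = nlab)
  s1 <- rep(0, nlab); s2 <- rep(0, nlab)
  if (length(lab)) {
    s1 <- rowsum_safe(v, lab, nlab)
    s2 <- rowsum_safe(v^2, lab, nlab)
  }
  m <- ifelse(n > 0, s1 / n, NA_real_)
  list(n = n, mean = m,
       sd = ifelse(n > 0, sqrt(pmax(s2 / n - m^2, 0)), NA_real_))
}

rowsum_safe <- function(v, g, nbins) {
  out <- rep(0, nbins)
  rs <- rowsum(v, g)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

# TRUE for foreground pixels deeper than erode_px from any mask edge,
# counting watershed boundaries between different labels as edges.
eroded_mask <- function(labels, erode_px) {
  if (erode_px <= 0) return(labels > 0)
  fg <- labels > 0
  nx <- nrow(labels); ny <- ncol(labels)
  boundary <- matrix(FALSE, nx, ny)
  d <- labels[-1, ] != labels[-nx, ] & labels[-1, ] > 0 & labels[-nx, ] > 0
  boundary[-1, ][d] <- TRUE; boundary[-nx, ][d] <- TRUE
  d <- labels[, -1] != labels[, -ny] & labels[, -1] > 0 & labels[, -ny] > 0
  boundary[, -1][d] <- TRUE; boundary[, -ny][d] <- TRUE
  dm <- EBImage::distmap(fg & !boundary)
  as.matrix(dm) > erode_px
}

#' Positivity call for a fluorescence channel
#'
#' A cell is positive iff its background-subtracted mean FI strictly exceeds
#' the channel threshold (a cell exactly at threshold is negative).
#'
#' @param mean_fi background-subtracted mean FI (vectorised)
#' @param threshold_policy either a fixed threshold in au, or
#'   `list(k = 5)` meaning `k` background SDs (then `background_sd` is
#'   required)
#' @param background_sd robust background SD used by the k-SD policy
#' @return logical vector
#' @examples
#' call_positive(c(99, 100, 101), 100)
#' @export
call_positive <- function(mean_fi, threshold_policy, background_sd = NULL) {
  thr <- resolve_threshold(threshold_policy, background_sd)
  mean_fi > thr
}

resolve_threshold <- function(policy, background_sd = NULL) {
  if (is.numeric(policy) && length(policy) == 1) return(policy)
  if (is.list(policy) && !is.null(policy$k)) {
    if (is.null(background_sd))
      config_error("k-SD threshold policy needs background_sd")
    return(policy$k * background_sd)
  }
  config_error("unresolved threshold policy: give a value or list(k = ...)")
}

#' Ordinary least-squares kinetic slope
#'
#' Fits `fi ~ t` by OLS with time in minutes and returns the slope (au/min)
#' and the coefficient of determination.  `r2` is defined as
#' `1 - SS_res/SS_tot`, with the 0/0 case of a constant, perfectly fitted
#' trace taken as 1.
#'
#' @param trace list or data.frame with `t` (seconds, strictly increasing)
#'   and `fi` (au)
#' @return named numeric `c(slope, r2)`
#' @examples
#' fit_slope(list(t = 60 * (0:4), fi = c(10, 20, 30, 40, 50)))
#' @export
fit_slope <- function(trace) {
  t_sec <- trace$t; fi <- trace$fi
  if (length(t_sec) < 2 || length(fi) != length(t_sec))
    param_error("a kinetic trace needs >= 2 (t, fi) points")
  if (any(diff(t_sec) <= 0))
    param_error("timestamps must be strictly increasing")
  tm <- t_sec / 60
  vt <- sum((tm - mean(tm))^2)
  if (vt == 0) param_error("constant time values")
  slope <- sum((tm - mean(tm)) * (fi - mean(fi))) / vt
  ss_tot <- sum((fi - mean(fi))^2)
  ss_res <- sum((fi - (mean(fi) + slope * (tm - mean(tm))))^2)
  r2 <- if (ss_tot <= 1e-12) 1 else 1 - ss_res / ss_tot
  c(slope = slope, r2 = r2)
}

#' Extract per-cell kinetic traces and fit slopes
#'
#' Measures every segmented cell on each frame of a timed series
#' (background-subtracted eroded-mask means) and fits the per-cell OLS
#' slope.
#'
#' @param seg a [segment_cells()] result from the same acquisition round
#' @param frames list of `list(t = seconds, image = matrix)` as produced by
#'   [render_kinetic_series()]
#' @param erode_px mask erosion depth passed to [measure_cells()]
#' @return `seg$cells` with `fda_slope` (au/min) and `fda_slope_r2`
#' @export
extract_traces <- function(seg, frames, erode_px = 3) {
  if (length(frames) < 2) param_error("need >= 2 kinetic frames")
  t_sec <- vapply(frames, function(f) f$t, numeric(1))
  fi <- vapply(frames, function(f) {
    m <- measure_cells(seg, f$image, erode_px = erode_px)
    # keep sign: slope estimation must see below-background fluctuations
    m$mean_fi_signed
  }, numeric(nrow(seg$cells)))
  if (nrow(seg$cells) == 1) fi <- matrix(fi, nrow = 1)
  out <- seg$cells
  fits <- t(apply(fi, 1, function(row) fit_slope(list(t = t_sec, fi = row))))
  out$fda_slope <- fits[, "slope"]
  out$fda_slope_r2 <- fits[, "r2"]
  out
}

#' Match the same physical cells across two acquisition rounds
#'
#' Round-2 centroids are first brought into the round-1 frame using the
#' saved stage positions, then cells are matched within the same picowell by
#' nearest centroid within `max_dist_px` (greedy on increasing distance).
#' Unmatched cells are returned flagged, never silently dropped.
#'
#' @param records_round1,records_round2 cell tables with `picowell_id`,
#'   `x`, `y` (round-specific measurement columns are carried through)
#' @param registry stage-position table: `round`, `field_id`, `x_um`,
#'   `y_um`
#' @param microns_per_pixel image scale for converting the stage delta
#' @param max_dist_px maximum matching distance; default 0.3 of a 21.5-px
#'   cell diameter
#' @param field_id field to link
#' @return list with `pairs` (data.frame `idx1`, `idx2`, `dist_px`),
#'   `unmatched1`, `unmatched2` (integer indices)
#' @export
link_rounds <- function(records_round1, records_round2, registry,
                        microns_per_pixel = 0.65, max_dist_px = 6.5,
                        field_id = NULL) {
  if (is.null(field_id)) field_id <- registry$field_id[1]
  r1 <- registry[registry$round == 1 & registry$field_id == field_id, ]
  r2 <- registry[registry$round == 2 & registry$field_id == field_id, ]
  if (nrow(r1) != 1 || nrow(r2) != 1)
    param_error(sprintf("field '%s' missing from the stage registry",
                        field_id))
  dx <- (r2$x_um - r1$x_um) / microns_per_pixel
  dy <- (r2$y_um - r1$y_um) / microns_per_pixel
  x2 <- records_round2$x - dx
  y2 <- records_round2$y - dy

  cand <- do.call(rbind, lapply(seq_len(nrow(records_round1)), function(a) {
    b <- which(records_round2$picowell_id == records_round1$picowell_id[a])
    if (length(b) == 0) return(NULL)
    d <- sqrt((x2[b] - records_round1$x[a])^2 +
              (y2[b] - records_round1$y[a])^2)
    ok <- d <= max_dist_px
    if (!any(ok)) return(NULL)
    data.frame(idx1 = a, idx2 = b[ok], dist_px = d[ok])
  }))
  pairs <- data.frame(idx1 = integer(0), idx2 = integer(0),
                      dist_px = numeric(0))
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$dist_px), ]
    used1 <- logical(nrow(records_round1))
    used2 <- logical(nrow(records_round2))
    sel <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      a <- cand$idx1[k]; b <- cand$idx2[k]
      if (!used1[a] && !used2[b]) {
        used1[a] <- TRUE; used2[b] <- TRUE; sel[k] <- TRUE
      }
    }
    pairs <- cand[sel, ]
  }
  list(pairs = pairs,
       unmatched1 = setdiff(seq_len(nrow(records_round1)), pairs$idx1),
       unmatched2 = setdiff(seq_len(nrow(records_round2)), pairs$idx2))
}
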