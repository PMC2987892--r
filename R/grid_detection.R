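## Recovering the picowell lattice from a transmitted-light image.
##
## Pitch and orientation come from the autocorrelation of the
## mean-subtracted image (computed spectrally): a hexagonal wall lattice
## puts six first-order peaks around the origin at radius = pitch.  Peak
## positions are refined to sub-pixel precision by local intensity
## centroids, the lattice origin by maximising mean image brightness at the
## predicted well centres (wells are bright, walls dark).

fftshift2 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  m[c((floor(nx / 2) + 1):nx, 1:floor(nx / 2)),
    c((floor(ny / 2) + 1):ny, 1:floor(ny / 2))]
}

# Subpixel peak position: intensity centroid over a (2w+1)^2 window.
peak_centroid <- function(m, px, py, w = 3) {
  ix <- max(1, px - w):min(nrow(m), px + w)
  iy <- max(1, py - w):min(ncol(m), py + w)
  win <- m[ix, iy, drop = FALSE]
  win <- pmax(win - min(win), 0)
  s <- sum(win)
  if (s <= 0) return(c(px, py))
  c(sum(outer(ix, rep(1, length(iy))) * win) / s,
    sum(outer(rep(1, length(ix)), iy) * win) / s)
}

# Local maxima of matrix m above threshold (8-neighbourhood).
local_maxima <- function(m, thresh) {
  nx <- nrow(m); ny <- ncol(m)
  core <- m[2:(nx - 1), 2:(ny - 1)]
  ok <- core > thresh
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & core >= m[2:(nx - 1) + di, 2:(ny - 1) + dj]
  }
  which(ok, arr.ind = TRUE) + 1L
}

#' Detect the hexagonal picowell lattice
#'
#' Estimates pitch, orientation (modulo 60 degrees) and origin of the
#' picowell lattice from a transmitted-light image.
#'
#' @param transmitted_image numeric matrix (x, y)
#' @param microns_per_pixel image scale
#' @param min_pitch_px smallest lattice pitch considered, px
#' @param peak_snr minimum ratio of the first-order autocorrelation peak to
#'   the annulus noise floor; below it a
#'   `picocyte_detection_error` is raised
#' @return a [picowell_grid()] whose `sites` enumerate all lattice sites
#'   with centres inside the image
#' @examples
#' sc <- sample_population(untreated_tmrm_population(), n_picowells = 16,
#'                         occupancy_mean = 3, seed = 1)
#' img <- render_channel(sc, "transmitted", seed = 1)
#' g <- detect_lattice(img, 0.65)
#' abs(g$pitch_px - sc$grid$pitch_px) < 1
#' @export
detect_lattice <- function(transmitted_image, microns_per_pixel,
                           min_pitch_px = 12, peak_snr = 5) {
  img <- transmitted_image
  # centre crop to a power-friendly size: autocorrelation peaks only need a
  # representative region
  nx <- nrow(img); ny <- ncol(img)
  cx <- min(2^floor(log2(nx)), 2048); cy <- min(2^floor(log2(ny)), 2048)
  ox <- floor((nx - cx) / 2); oy <- floor((ny - cy) / 2)
  sub <- img[ox + seq_len(cx), oy + seq_len(cy)]
  m <- sub - mean(sub)
  P <- Mod(stats::fft(m))^2
  ac <- Re(stats::fft(P, inverse = TRUE)) / length(P)
  ac <- fftshift2(ac)
  c0 <- c(floor(cx / 2) + 1, floor(cy / 2) + 1)

  px <- rep.int(seq_len(cx), cy) - c0[1]
  py <- rep(seq_len(cy), each = cx) - c0[2]
  rad <- matrix(sqrt(px^2 + py^2), cx, cy)
  search <- rad >= min_pitch_px & rad <= min(cx, cy) / 2 - 2
  if (!any(search)) detection_error("image too small for lattice search")
  floor_mad <- stats::mad(ac[search])
  floor_med <- stats::median(ac[search])
  peak_val <- max(ac[search])
  if (peak_val < floor_med + peak_snr * floor_mad || floor_mad == 0)
    detection_error(sprintf(
      "no periodic lattice found (peak SNR %.2f below %.2f)",
      if (floor_mad > 0) (peak_val - floor_med) / floor_mad else 0,
      peak_snr))

  # strongest non-DC peak fixes the first-order radius; collect the ring
  masked <- ac
  masked[!search] <- -Inf
  idx <- which(masked == peak_val, arr.ind = TRUE)[1, ]
  r1 <- rad[idx[1], idx[2]]
  ring <- masked
  ring[rad < 0.8 * r1 | rad > 1.25 * r1] <- -Inf
  lm <- local_maxima(ring, floor_med + 0.5 * (peak_val - floor_med))
  if (nrow(lm) < 2) detection_error("fewer than two lattice peaks found")
  pk <- t(apply(lm, 1, function(p) peak_centroid(ac, p[1], p[2])))
  vx <- pk[, 1] - c0[1]; vy <- pk[, 2] - c0[2]
  # canonicalise to upper half plane, deduplicate +/- pairs
  flip <- vy < 0 | (abs(vy) < 1e-9 & vx < 0)
  vx[flip] <- -vx[flip]; vy[flip] <- -vy[flip]
  ang <- atan2(vy, vx)
  keep <- !duplicated(round(ang / (pi / 36)))
  vx <- vx[keep]; vy <- vy[keep]; ang <- ang[keep]
  val <- ring[lm[keep, , drop = FALSE]]

  a1 <- c(vx[which.max(val)], vy[which.max(val)])
  th1 <- atan2(a1[2], a1[1])
  dth <- (ang - th1) %% pi
  cand <- which(abs(dth - pi / 3) < pi / 18)
  a2 <- if (length(cand)) {
    k <- cand[which.max(val[cand])]
    c(vx[k], vy[k])
  } else { # fall back to the hexagonal partner implied by a1
    rot <- pi / 3
    c(cos(rot) * a1[1] - sin(rot) * a1[2],
      sin(rot) * a1[1] + cos(rot) * a1[2])
  }
  pitch_px <- mean(c(sqrt(sum(a1^2)), sqrt(sum(a2^2))))
  orientation <- min(atan2(a1[2], a1[1]) %% (pi / 3),
                     atan2(a2[2], a2[1]) %% (pi / 3))

  origin <- refine_origin(img, pitch_px, orientation)
  grid_from_parameters(pitch_px, orientation, origin,
                       microns_per_pixel, dim(img))
}

# Enumerate all sites with centres inside dim for a parametric lattice.
grid_from_parameters <- function(pitch_px, orientation, origin,
                                 microns_per_pixel, dim) {
  B <- lattice_basis(pitch_px, orientation)
  Binv <- solve(B)
  corners <- rbind(c(1, 1), c(dim[1], 1), c(1, dim[2]), c(dim[1], dim[2]))
  uv <- t(Binv %*% (t(corners) - origin))
  ir <- floor(min(uv[, 1]) - 1):ceiling(max(uv[, 1]) + 1)
  jr <- floor(min(uv[, 2]) - 1):ceiling(max(uv[, 2]) + 1)
  ij <- expand.grid(i = ir, j = jr)
  x <- origin[1] + ij$i * B[1, 1] + ij$j * B[1, 2]
  y <- origin[2] + ij$i * B[2, 1] + ij$j * B[2, 2]
  keep <- x >= 1 & x <= dim[1] & y >= 1 & y <= dim[2]
  sites <- data.frame(i = ij$i[keep], j = ij$j[keep],
                      picowell_id = picowell_id(ij$i[keep], ij$j[keep]),
                      x = x[keep], y = y[keep], stringsAsFactors = FALSE)
  structure(list(pitch_um = pitch_px * microns_per_pixel,
                 pitch_px = pitch_px,
                 microns_per_pixel = microns_per_pixel,
                 orientation = orientation, origin = origin, basis = B,
                 sites = sites, image_shape = dim),
            class = "picowell_grid")
}

# Lattice origin by exhaustive search over one unit cell.  The criterion
# contrasts smoothed image brightness at the predicted well centres against
# the three wall-midpoint sublattices (centres shifted by a1/2, a2/2,
# (a2-a1)/2): walls are dark regardless of how many cells occupy the wells,
# so the contrast is peaked at the true origin at any occupancy, with ~2x
# separation from the strongest false optimum.  The grid step stays under
# the peak width (wall band + smoothing), and the winner is polished by
# Nelder-Mead.  Pure centre-brightness scoring and Fourier-phase origin
# estimation were both tried and rejected: the former develops
# near-degenerate false optima at high occupancy, the latter inherits
# biases of up to ~0.1 period from the coherent part of the cell-coverage
# signal.
refine_origin <- function(img, pitch_px, orientation) {
  B <- lattice_basis(pitch_px, orientation)
  nx <- nrow(img); ny <- ncol(img)
  sm <- as.matrix(EBImage::gblur(img, sigma = max(2, pitch_px / 40)))
  half <- cbind(B[, 1] / 2, B[, 2] / 2, (B[, 2] - B[, 1]) / 2)
  g <- grid_from_parameters(pitch_px, orientation, c(0, 0), 1, c(nx, ny))
  s <- g$sites
  pad <- 1.6 * pitch_px
  s <- s[s$x > pad & s$x < nx - pad & s$y > pad & s$y < ny - pad, ]
  if (nrow(s) == 0) detection_error("image too small to refine the origin")
  if (nrow(s) > 400) # deterministic thinning: detection has no RNG
    s <- s[unique(round(seq(1, nrow(s), length.out = 400))), ]
  score <- function(off) {
    centres <- mean(bilinear(sm, s$x + off[1], s$y + off[2]))
    walls <- mean(vapply(1:3, function(k)
      mean(bilinear(sm, s$x + off[1] + half[1, k],
                    s$y + off[2] + half[2, k])), numeric(1)))
    centres - walls
  }
  step <- max(0.02, min(0.08, 3.2 / pitch_px))
  uv <- as.matrix(expand.grid(u = seq(0, 1 - step / 2, by = step),
                              v = seq(0, 1 - step / 2, by = step)))
  offs <- uv %*% t(B)
  vals <- apply(offs, 1, score)
  best <- offs[which.max(vals), ]
  opt <- stats::optim(best, function(o) -score(o), method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-8))
  opt$par
}

#' Tessellate the image into per-picowell ROIs
#'
#' Voronoi tessellation of the lattice sites clipped to the image: every
#' pixel is labelled with its nearest site.  Sites whose full hexagonal ROI
#' does not fit inside the image are flagged `interior = FALSE` and are
#' excluded from measurement (edge picowells would otherwise bias area and
#' occupancy statistics).
#'
#' @param grid a [picowell_grid()]
#' @param image_shape c(nx, ny) of the image to tessellate
#' @return object of class `roi_map`: list with `labels` (integer matrix;
#'   0 = outside any enumerated ROI), `sites` (data.frame: `roi`,
#'   `picowell_id`, `i`, `j`, `x`, `y`, `interior`, `area_px`), `grid`,
#'   `image_shape`
#' @export
build_roi_map <- function(grid, image_shape) {
  if (grid$pitch_px <= 2) param_error("degenerate grid: pitch too small")
  flds <- lattice_label_fields(grid, image_shape)
  key <- paste(flds$i, flds$j, sep = ",")
  skey <- paste(grid$sites$i, grid$sites$j, sep = ",")
  # enumerate from observed keys so detected grids and generated grids both
  # work; order by (j, i) for stable ids
  s <- grid$sites[order(grid$sites$j, grid$sites$i), , drop = FALSE]
  lab <- match(key, paste(s$i, s$j, sep = ","))
  lab[is.na(lab)] <- 0L
  labels <- matrix(lab, image_shape[1], image_shape[2])
  rh <- grid$pitch_px / sqrt(3) + 1 # hexagon circumradius
  interior <- s$x - rh >= 1 & s$x + rh <= image_shape[1] &
    s$y - rh >= 1 & s$y + rh <= image_shape[2]
  area <- tabulate(labels, nbins = nrow(s))
  sites <- data.frame(roi = seq_len(nrow(s)), picowell_id = s$picowell_id,
                      i = s$i, j = s$j, x = s$x, y = s$y,
                      interior = interior, area_px = area,
                      stringsAsFactors = FALSE)
  structure(list(labels = labels, sites = sites, grid = grid,
                 image_shape = image_shape,
                 wall_gap = flds$d2 - flds$d1), # for analytic wall masking
            class = "roi_map")
}

#' @export
print.roi_map <- function(x, ...) {
  cat(sprintf("roi_map: %d ROIs (%d interior), image %d x %d px\n",
              nrow(x$sites), sum(x$sites$interior),
              x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Flag occupied picowells
#'
#' A picowell is occupied iff its foreground area (pixels deviating from the
#' background by more than `k_sd` robust SDs, on the dark side for
#' transmitted light) reaches at least one minimal cell footprint.
#'
#' @param roi_map a [build_roi_map()] result
#' @param image image sharing `roi_map$image_shape`
#' @param dark_cells TRUE when foreground is darker than background
#'   (transmitted light); FALSE for fluorescence
#' @param min_cell_area_px minimal cell footprint in pixels
#' @param k_sd threshold in robust background SDs
#' @param open_radius radius (px) of the opening brush removing thin wall
#'   bands from the foreground
#' @return data.frame `sites` columns plus `fg_px` and logical `occupied`,
#'   with attribute `mask` (logical foreground matrix)
#' @export
occupancy <- function(roi_map, image, dark_cells = TRUE,
                      min_cell_area_px = 60, k_sd = 5, open_radius = 4) {
  if (!all(dim(image) == roi_map$image_shape))
    param_error("image and roi_map shapes differ")
  bg <- stats::median(image)
  s <- stats::mad(image)
  if (s == 0) s <- 1
  fg <- if (dark_cells) image < bg - k_sd * s else image > bg + k_sd * s
  if (any(fg)) {
    brush <- EBImage::makeBrush(2 * open_radius + 1, shape = "disc")
    fg <- EBImage::opening(fg, brush) > 0
  }
  cnt <- tabulate(roi_map$labels[fg], nbins = nrow(roi_map$sites))
  out <- roi_map$sites
  out$fg_px <- cnt
  out$occupied <- cnt >= min_cell_area_px
  attr(out, "mask") <- fg
  out
}
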