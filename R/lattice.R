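## Hexagonal picowell lattice: parametric grid, site enumeration and the
## pixel -> nearest-lattice-site fields that both rendering and ROI
## tessellation are built on.
##
## Conventions: images are numeric matrices indexed [x, y] (x = horizontal
## axis, first dimension), pixel centres at integer coordinates starting at 1.
## The lattice basis is a1 = pitch * (cos t, sin t),
## a2 = pitch * (cos(t + 60d), sin(t + 60d)); a site has integer lattice
## indices (i, j) with position origin + i * a1 + j * a2.

lattice_basis <- function(pitch_px, orientation) {
  t1 <- orientation
  t2 <- orientation + pi / 3
  cbind(a1 = pitch_px * c(cos(t1), sin(t1)),
        a2 = pitch_px * c(cos(t2), sin(t2)))
}

#' Parametric hexagonal picowell grid
#'
#' Describes a hexagonal lattice of picowell centres: pitch (centre-to-centre
#' spacing), orientation, and pixel origin.  `n_cols` x `n_rows` sites are
#' enumerated row by row with alternate-row stagger so the site cloud stays
#' roughly rectangular.
#'
#' @param pitch_um centre-to-centre pitch in microns (20 or 100 in the
#'   supported devices)
#' @param microns_per_pixel image scale, microns per pixel
#' @param n_cols,n_rows number of lattice columns/rows to enumerate
#' @param orientation lattice orientation in radians, reported modulo 60
#'   degrees
#' @param origin pixel coordinates of the (0, 0) site; default leaves one
#'   pitch of margin so every enumerated site has a complete hexagonal ROI
#'   inside the suggested image
#' @return an object of class `picowell_grid`: list with `pitch_um`,
#'   `pitch_px`, `microns_per_pixel`, `orientation`, `origin`, `basis`
#'   (2 x 2, columns a1/a2), `sites` (data.frame `i`, `j`, `picowell_id`,
#'   `x`, `y`) and `image_shape` (suggested c(nx, ny))
#' @examples
#' g <- picowell_grid(100, 0.65, n_cols = 4, n_rows = 4)
#' nrow(g$sites)
#' @export
picowell_grid <- function(pitch_um, microns_per_pixel, n_cols, n_rows,
                          orientation = 0, origin = NULL) {
  if (pitch_um <= 0 || microns_per_pixel <= 0)
    param_error("pitch_um and microns_per_pixel must be positive")
  pitch_px <- pitch_um / microns_per_pixel
  B <- lattice_basis(pitch_px, orientation)
  margin <- pitch_px * 1.25
  if (is.null(origin)) origin <- c(margin, margin)

  ij <- do.call(rbind, lapply(seq_len(n_rows) - 1L, function(j) {
    i0 <- -floor(j / 2) # stagger keeps x extent compact
    cbind(i = i0 + seq_len(n_cols) - 1L, j = j)
  }))
  xy <- cbind(origin[1] + ij[, 1] * B[1, 1] + ij[, 2] * B[1, 2],
              origin[2] + ij[, 1] * B[2, 1] + ij[, 2] * B[2, 2])
  # rotated bases can push staggered rows below the margin: shift the whole
  # cloud (and the origin with it) so every site keeps the full margin
  shift <- pmax(margin - apply(xy, 2, min), 0)
  origin <- origin + shift
  xy <- sweep(xy, 2, shift, "+")
  sites <- data.frame(i = ij[, 1], j = ij[, 2],
                      picowell_id = picowell_id(ij[, 1], ij[, 2]),
                      x = xy[, 1], y = xy[, 2],
                      stringsAsFactors = FALSE)
  shape <- c(ceiling(max(xy[, 1]) + margin), ceiling(max(xy[, 2]) + margin))
  structure(list(pitch_um = pitch_um, pitch_px = pitch_px,
                 microns_per_pixel = microns_per_pixel,
                 orientation = orientation, origin = origin, basis = B,
                 sites = sites, image_shape = shape),
            class = "picowell_grid")
}

picowell_id <- function(i, j) sprintf("w%+04d%+04d", i, j)

#' @export
print.picowell_grid <- function(x, ...) {
  cat(sprintf(
    "picowell_grid: pitch %.4g um (%.2f px), orientation %.2f deg, %d sites\n",
    x$pitch_um, x$pitch_px, x$orientation * 180 / pi, nrow(x$sites)))
  invisible(x)
}

# For every pixel of a dim = c(nx, ny) image, the lattice indices (i, j) of
# the nearest site plus distances to the nearest (d1) and second-nearest (d2)
# sites.  O(pixels): nearest site is found among the 3x3 block of lattice
# candidates around the fractional lattice coordinates of the pixel.
lattice_label_fields <- function(grid, dim) {
  nx <- dim[1]; ny <- dim[2]
  n <- nx * ny
  px <- rep.int(seq_len(nx), ny)
  py <- rep(seq_len(ny), each = nx)
  B <- grid$basis
  Binv <- solve(B)
  dx <- px - grid$origin[1]
  dy <- py - grid$origin[2]
  u <- Binv[1, 1] * dx + Binv[1, 2] * dy
  v <- Binv[2, 1] * dx + Binv[2, 2] * dy
  i0 <- floor(u); j0 <- floor(v)
  best1 <- rep.int(Inf, n); best2 <- rep.int(Inf, n)
  bi <- integer(n); bj <- integer(n)
  for (di in -1:1) for (dj in -1:1) {
    ii <- i0 + di; jj <- j0 + dj
    sx <- grid$origin[1] + ii * B[1, 1] + jj * B[1, 2]
    sy <- grid$origin[2] + ii * B[2, 1] + jj * B[2, 2]
    d2v <- (px - sx)^2 + (py - sy)^2
    best2 <- pmin(best2, d2v)
    sel <- d2v < best1
    if (any(sel)) {
      best2[sel] <- best1[sel]
      best1[sel] <- d2v[sel]
      bi[sel] <- ii[sel]; bj[sel] <- jj[sel]
    }
  }
  list(i = matrix(bi, nx, ny), j = matrix(bj, nx, ny),
       d1 = matrix(sqrt(best1), nx, ny), d2 = matrix(sqrt(best2), nx, ny))
}

# Wall mask: band of total width `wall_px` along the Voronoi boundaries of
# the lattice (moving off the boundary by s changes d2 - d1 by ~2s).
lattice_wall_mask <- function(fields, wall_px) {
  (fields$d2 - fields$d1) < wall_px
}
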