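## Ground-truthed synthetic picowell fields.
##
## The generator emulates what the analysis assumes about real acquisitions:
## a 14-bit camera (values 0..16383), a dark hexagonal wall lattice in
## transmitted light, round suspension cells rendered as disks whose
## noise-free within-mask mean / SD equal the cell's true channel mean / FI
## SD, an isotropic Gaussian PSF, and Poisson shot noise plus Gaussian read
## noise.  Every cell carries its ground truth so recovery by the analysis
## pipeline can be scored exactly.

default_optics <- function() {
  list(
    fluor_background = 50,    # au, uniform fluorescence background
    read_sd = 20,             # au, Gaussian read noise SD
    gain = 1,                 # au per photoelectron for shot noise
    psf_sigma = 1,            # px, isotropic Gaussian PSF
    trans_background = 2000,  # au, transmitted-light background
    wall_factor = 0.5,        # wall brightness relative to background
    cell_factor = 0.65,       # cell-body brightness relative to background
    trans_cell_sd = 30,       # au, transmitted within-cell texture
    wall_px = 4,              # px, rendered wall band width
    fitc_pos = 900,  fitc_pos_sd = 90, fitc_neg = 15, fitc_neg_sd = 5,
    pi_pos   = 1200, pi_pos_sd  = 120, pi_neg   = 10, pi_neg_sd  = 4,
    fitc_within_sd_frac = 0.15, # within-cell SD as fraction of level
    fda_baseline = 30         # au, FDA signal at t = 0
  )
}

capacity_for_pitch <- function(pitch_um) if (pitch_um < 50) 1L else 20L

#' Sample a ground-truthed picowell-field population
#'
#' Draws per-picowell occupancies from a capacity-truncated Poisson, assigns
#' each cell to a subgroup by multinomial sampling on the mixture fractions,
#' draws its true channel parameters from the subgroup's truncated normal
#' distributions, and places non-overlapping cell disks inside the wells.
#'
#' @param params a [subgroup_params()] table
#' @param n_cells stop after exactly this many cells (filling wells in
#'   lattice order); give either `n_cells` or `n_picowells`
#' @param occupancy_mean mean of the (untruncated) Poisson occupancy,
#'   cells/picowell
#' @param grid optional [picowell_grid()]; default builds one large enough
#'   for the request at `pitch_um` / `microns_per_pixel`
#' @param seed integer seed; mandatory for reproducible scenes
#' @param pitch_um,microns_per_pixel geometry used when `grid` is NULL
#' @param n_picowells fill exactly this many picowells (each with a
#'   truncated-Poisson count)
#' @param capacity per-picowell capacity; default 20 for 100-um pitch and 1
#'   for 20-um pitch
#' @param cell_radius_um cell disk radius (round suspension cells)
#' @param max_overlap maximum allowed pairwise overlap, as a fraction of a
#'   cell's area
#' @param optics render settings; see `picocyte:::default_optics`
#' @return object of class `field_scene`: list with `grid`, `cells`
#'   (ground-truth data.frame), `microns_per_pixel`, `image_shape`,
#'   `bit_depth` (14), `capacity`, `optics`, `timepoint_h`, `seed`
#' @examples
#' sc <- sample_population(untreated_tmrm_population(), n_cells = 20,
#'                         occupancy_mean = 5, seed = 1)
#' nrow(sc$cells)
#' @export
sample_population <- function(params, n_cells = NULL, occupancy_mean = 9.6,
                              grid = NULL, seed = NULL,
                              pitch_um = 100, microns_per_pixel = 0.65,
                              n_picowells = NULL, capacity = NULL,
                              cell_radius_um = 7, max_overlap = 0.1,
                              optics = default_optics()) {
  validate_subgroup_params(params)
  if (is.null(n_cells) && is.null(n_picowells))
    param_error("give n_cells or n_picowells")
  if (!is.null(n_cells) && n_cells < 1) param_error("n_cells must be >= 1")
  if (occupancy_mean <= 0) param_error("occupancy_mean must be positive")
  if (!is.null(grid)) pitch_um <- grid$pitch_um
  capacity <- capacity %||% capacity_for_pitch(pitch_um)
  if (occupancy_mean > capacity)
    param_error(sprintf(
      "requested occupancy %.3g exceeds picowell capacity %d", occupancy_mean,
      capacity))

  mu_occ <- tpois_mean(occupancy_mean, capacity)
  if (is.null(grid)) {
    need <- n_picowells %||% ceiling(n_cells / mu_occ * 1.25 + 4)
    nc <- ceiling(sqrt(need))
    nr <- ceiling(need / nc)
    grid <- picowell_grid(pitch_um, microns_per_pixel, nc, nr)
  }
  r_px <- cell_radius_um / grid$microns_per_pixel
  usable <- grid$pitch_px / 2 - r_px - default_optics()$wall_px / 2
  if (usable < 0)
    param_error("cell radius does not fit inside a picowell at this pitch")

  with_seed(seed, {
    sites <- grid$sites
    n_sites <- if (!is.null(n_picowells)) {
      if (n_picowells > nrow(sites))
        param_error("grid has fewer sites than n_picowells")
      n_picowells
    } else nrow(sites)
    counts <- rtpois(n_sites, occupancy_mean, capacity)
    if (!is.null(n_cells)) {
      cum <- cumsum(counts)
      if (cum[length(cum)] < n_cells)
        param_error("grid too small for n_cells; supply a larger grid")
      k <- which(cum >= n_cells)[1]
      counts[k] <- counts[k] - (cum[k] - n_cells)
      if (k < n_sites) counts[(k + 1):n_sites] <- 0L
    }
    total <- sum(counts)
    sub_idx <- sample.int(nrow(params), total, replace = TRUE,
                          prob = params$fraction)
    off <- place_all(counts, r_px, usable, max_overlap)
    well <- rep(seq_len(n_sites), counts)
    cells <- data.frame(
      cell_id = sprintf("c%05d", seq_len(total)),
      i = sites$i[well], j = sites$j[well],
      picowell_id = sites$picowell_id[well],
      x = sites$x[well] + off[, 1], y = sites$y[well] + off[, 2],
      radius_px = r_px,
      subgroup = params$name[sub_idx],
      true_tmrm_mean = rtnorm(total, params$tmrm_mean_fi[sub_idx],
                              params$tmrm_mean_fi_sd[sub_idx]),
      true_tmrm_sd = rtnorm(total, params$tmrm_fi_sd[sub_idx],
                            params$tmrm_fi_sd_sd[sub_idx]),
      true_fda_slope = rtnorm(total, params$fda_slope[sub_idx],
                              params$fda_slope_sd[sub_idx]),
      true_annexin = params$annexin_positive[sub_idx],
      true_pi = params$pi_positive[sub_idx],
      stringsAsFactors = FALSE)
    structure(list(grid = grid, cells = cells,
                   microns_per_pixel = grid$microns_per_pixel,
                   image_shape = grid$image_shape, bit_depth = 14L,
                   capacity = capacity, optics = optics,
                   timepoint_h = 0, seed = seed),
              class = "field_scene")
  })
}

#' @export
print.field_scene <- function(x, ...) {
  cat(sprintf(
    "field_scene: %d cells in %d occupied picowells, image %d x %d px, t = %g h\n",
    nrow(x$cells), length(unique(x$cells$picowell_id)),
    x$image_shape[1], x$image_shape[2], x$timepoint_h))
  invisible(x)
}

## Disk placement ----------------------------------------------------------

# Minimum centre distance so two equal disks overlap by at most `max_overlap`
# of one disk's area (lens area, solved numerically).
min_centre_distance <- function(r, max_overlap) {
  if (max_overlap >= 1) return(0)
  lens <- function(d) {
    if (d >= 2 * r) return(0)
    2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  }
  target <- max_overlap * pi * r^2
  stats::uniroot(function(d) lens(d) - target, c(1e-9, 2 * r))$root
}

# Random sequential placement of n disk centres within a disc of radius
# `usable`, pairwise centre distance >= dmin against `existing` and earlier
# placements; dmin relaxes geometrically if the well is crowded so
# placement always terminates.
place_in_well <- function(n, dmin, usable, existing = NULL) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  pts <- if (is.null(existing)) matrix(numeric(0), 0, 2) else existing
  out <- matrix(NA_real_, n, 2)
  d <- dmin
  for (k in seq_len(n)) {
    placed <- FALSE
    for (trial in 1:400) {
      th <- runif(1, 0, 2 * pi); rr <- usable * sqrt(runif(1))
      p <- c(rr * cos(th), rr * sin(th))
      if (nrow(pts) == 0 ||
          min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= d^2) {
        placed <- TRUE; break
      }
      if (trial %% 100 == 0) d <- d * 0.9 # crowded: relax gradually
    }
    if (!placed) p <- c(rr * cos(th), rr * sin(th)) # accept last candidate
    out[k, ] <- p
    pts <- rbind(pts, p)
  }
  out
}

place_all <- function(counts, r_px, usable, max_overlap) {
  dmin <- min_centre_distance(r_px, max_overlap)
  do.call(rbind, lapply(counts, place_in_well, dmin = dmin, usable = usable))
}

## Rendering ---------------------------------------------------------------

# Add per-cell disks to a zero canvas; each cell's noise-free within-mask
# sample mean / population SD equal `level` / `within_sd` exactly (gamma
# draws, affinely standardised; gamma keeps the support non-negative even
# when the SD is a large fraction of the mean).
render_cell_disks <- function(canvas, cells, level, within_sd,
                              overwrite = FALSE) {
  nx <- nrow(canvas); ny <- ncol(canvas)
  for (k in seq_len(nrow(cells))) {
    lv <- level[k]
    if (overwrite == FALSE && lv <= 0) next
    x <- cells$x[k]; y <- cells$y[k]; r <- cells$radius_px[k]
    if (x - r < 1 || y - r < 1 || x + r > nx || y + r > ny)
      render_error(sprintf("cell %s extends outside the image",
                           cells$cell_id[k]))
    ix <- floor(x - r):ceiling(x + r)
    iy <- floor(y - r):ceiling(y + r)
    gx <- rep.int(ix, length(iy)); gy <- rep(iy, each = length(ix))
    inside <- (gx - x)^2 + (gy - y)^2 <= r^2
    gx <- gx[inside]; gy <- gy[inside]
    np <- length(gx)
    if (np == 0) next
    sdv <- within_sd[k]
    v <- if (sdv > 0 && np >= 2 && lv > 0) {
      g <- rgamma(np, shape = (lv / sdv)^2, scale = sdv^2 / lv)
      s <- pop_sd(g)
      vv <- if (s > 0) lv + (g - mean(g)) * (sdv / s) else rep(lv, np)
      if (any(vv < 0)) { # clamp, then restore the exact mask mean
        vv <- pmax(vv, 0)
        for (it in 1:25) {
          vv <- pmax(vv + (lv - mean(vv)), 0)
          if (abs(mean(vv) - lv) < 1e-9) break
        }
      }
      vv
    } else rep(max(lv, 0), np)
    idx <- cbind(gx, gy)
    canvas[idx] <- if (overwrite) v else canvas[idx] + v
  }
  canvas
}

apply_camera <- function(img, optics, noise, psf) {
  if (psf && optics$psf_sigma > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = optics$psf_sigma))
  img <- pmax(img, 0)
  if (noise) {
    n <- length(img)
    shot <- rpois(n, lambda = as.vector(img) / optics$gain) * optics$gain
    img <- matrix(shot + rnorm(n, 0, optics$read_sd), nrow(img), ncol(img))
    img <- round(img)
  }
  matrix(clip14(img), nrow(img), ncol(img))
}

#' Render one channel of a synthetic field
#'
#' Transmitted light shows the dark hexagonal wall lattice with cells as
#' darker disks; fluorescence channels show each cell as a disk over a
#' uniform background, with the cell's true mean / FI SD realised exactly
#' before PSF blur and camera noise.
#'
#' @param scene a [sample_population()] scene
#' @param channel one of `"transmitted"`, `"TMRM"`, `"FITC"`, `"PI"`
#' @param noise,psf logical switches for camera noise and PSF blur
#' @param seed integer seed for the render draws
#' @return numeric matrix, dim `scene$image_shape`, values in 0..16383
#' @examples
#' sc <- sample_population(untreated_tmrm_population(), n_cells = 5,
#'                         occupancy_mean = 2, seed = 1)
#' img <- render_channel(sc, "TMRM", noise = FALSE, psf = FALSE, seed = 1)
#' @export
render_channel <- function(scene, channel = c("transmitted", "TMRM",
                                              "FITC", "PI"),
                           noise = TRUE, psf = TRUE, seed = NULL) {
  channel <- match.arg(channel)
  op <- scene$optics
  cells <- scene$cells
  dim <- scene$image_shape
  with_seed(seed, {
    if (channel == "transmitted") {
      img <- matrix(op$trans_background, dim[1], dim[2])
      flds <- lattice_label_fields(scene$grid, dim)
      img[lattice_wall_mask(flds, op$wall_px)] <-
        op$trans_background * op$wall_factor
      lvl <- rep(op$trans_background * op$cell_factor, nrow(cells))
      img <- render_cell_disks(img, cells, lvl,
                               rep(op$trans_cell_sd, nrow(cells)),
                               overwrite = TRUE)
    } else {
      lvl <- switch(channel,
        TMRM = cells$true_tmrm_mean,
        FITC = ifelse(cells$true_annexin,
                      rtnorm(nrow(cells), op$fitc_pos, op$fitc_pos_sd),
                      rtnorm(nrow(cells), op$fitc_neg, op$fitc_neg_sd)),
        PI   = ifelse(cells$true_pi,
                      rtnorm(nrow(cells), op$pi_pos, op$pi_pos_sd),
                      rtnorm(nrow(cells), op$pi_neg, op$pi_neg_sd)))
      wsd <- switch(channel,
        TMRM = cells$true_tmrm_sd,
        FITC = op$fitc_within_sd_frac * lvl,
        PI   = op$fitc_within_sd_frac * lvl)
      img <- render_cell_disks(matrix(0, dim[1], dim[2]), cells, lvl, wsd)
      img <- img + op$fluor_background
    }
    apply_camera(img, op, noise, psf)
  })
}

#' Render a timed FDA hydrolysis series
#'
#' Frame k shows each cell at `FI(t) = baseline + slope * t` (t in minutes),
#' floored at 0.  Cells with a compromised membrane (PI positive) do not
#' accumulate hydrolysed fluorescein: their slope is forced to <= 0.
#'
#' @inheritParams render_channel
#' @param n_frames number of frames (>= 2)
#' @param dt frame spacing in seconds
#' @return list of `n_frames` elements, each `list(t = seconds, image = matrix)`
#' @export
render_kinetic_series <- function(scene, n_frames = 5, dt = 60,
                                  noise = TRUE, psf = TRUE, seed = NULL) {
  if (n_frames < 2) param_error("n_frames must be >= 2")
  if (dt <= 0) param_error("dt must be positive")
  op <- scene$optics
  cells <- scene$cells
  slope <- ifelse(cells$true_pi, pmin(cells$true_fda_slope, 0),
                  cells$true_fda_slope)
  with_seed(seed, {
    lapply(seq_len(n_frames) - 1L, function(k) {
      t_sec <- k * dt
      lvl <- pmax(op$fda_baseline + slope * (t_sec / 60), 0)
      wsd <- op$fitc_within_sd_frac * lvl + 2
      img <- render_cell_disks(matrix(0, scene$image_shape[1],
                                      scene$image_shape[2]),
                               cells, lvl, wsd)
      img <- img + op$fluor_background
      list(t = t_sec, image = apply_camera(img, op, noise, psf))
    })
  })
}

#' Simulate 48-hour per-picowell growth
#'
#' Each occupied picowell's count is multiplied by a growth ratio drawn from
#' a normal truncated at 0, rounded, and capped at the picowell capacity;
#' colonies remain confined to their picowell.  New cells clone the ground
#' truth of a random parent in the same well; shrinkage removes a random
#' subset.
#'
#' @param scene_t0 scene at time 0
#' @param ratio_mean,ratio_sd growth-ratio distribution (48 h count / 0 h
#'   count)
#' @param seed integer seed
#' @return a `field_scene` at `timepoint_h = 48` on the same grid
#' @export
simulate_growth <- function(scene_t0, ratio_mean = 1.26, ratio_sd = 0.71,
                            seed = NULL) {
  if (ratio_mean <= 0) param_error("ratio_mean must be positive")
  if (ratio_sd < 0) param_error("ratio_sd must be >= 0")
  cells <- scene_t0$cells
  r_px <- if (nrow(cells)) cells$radius_px[1] else 1
  usable <- scene_t0$grid$pitch_px / 2 - r_px - scene_t0$optics$wall_px / 2
  dmin <- min_centre_distance(r_px, 0.1)
  sites <- scene_t0$grid$sites
  with_seed(seed, {
    out <- vector("list", nrow(sites))
    for (s in seq_len(nrow(sites))) {
      wc <- cells[cells$picowell_id == sites$picowell_id[s], , drop = FALSE]
      n0 <- nrow(wc)
      if (n0 == 0) next
      r <- rtnorm(1, ratio_mean, ratio_sd)
      n48 <- min(round(n0 * r), scene_t0$capacity)
      if (n48 <= n0) {
        out[[s]] <- wc[sample.int(n0, n48), , drop = FALSE]
      } else {
        add <- n48 - n0
        parents <- wc[sample.int(n0, add, replace = TRUE), , drop = FALSE]
        exist <- cbind(wc$x - sites$x[s], wc$y - sites$y[s])
        off <- place_in_well(add, dmin, usable, existing = exist)
        parents$x <- sites$x[s] + off[, 1]
        parents$y <- sites$y[s] + off[, 2]
        parents$cell_id <- sprintf("%s_d%02d", parents$cell_id, seq_len(add))
        out[[s]] <- rbind(wc, parents)
      }
    }
    scene48 <- scene_t0
    scene48$cells <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    if (is.null(scene48$cells))
      scene48$cells <- cells[0, , drop = FALSE]
    rownames(scene48$cells) <- NULL
    scene48$timepoint_h <- 48
    scene48
  })
}

#' Translate a scene (stage move)
#'
#' Shifts the lattice origin and all cell centroids by `(dx, dy)` pixels,
#' emulating re-imaging of the same field at a slightly different stage
#' position.
#'
#' @param scene a `field_scene`
#' @param dx,dy shift in pixels
#' @return shifted `field_scene`
#' @export
translate_scene <- function(scene, dx, dy) {
  scene$grid$origin <- scene$grid$origin + c(dx, dy)
  scene$grid$sites$x <- scene$grid$sites$x + dx
  scene$grid$sites$y <- scene$grid$sites$y + dy
  scene$cells$x <- scene$cells$x + dx
  scene$cells$y <- scene$cells$y + dy
  scene
}

#' Render the two-round multi-parametric acquisition
#'
#' Round 1 images the field in transmitted light, TMRM and Annexin V-FITC;
#' the stage then moves (jitter), FDA + PI are introduced, and round 2
#' re-images the same field in transmitted light, PI and a timed FDA series.
#' Stage positions for both rounds are recorded in a registry, as saved
#' stage coordinates would be.
#'
#' @param scene a `field_scene`
#' @param seed integer seed
#' @param jitter_px SD (px) of the random stage offset between rounds
#' @param n_frames,dt FDA series timing
#' @param noise,psf camera switches
#' @return list with `round1` (transmitted, tmrm, fitc), `round2`
#'   (transmitted, pi, fda series), `registry` (data.frame: round, field_id,
#'   x_um, y_um)
#' @export
render_rounds <- function(scene, seed = NULL, jitter_px = 2,
                          n_frames = 5, dt = 60, noise = TRUE, psf = TRUE) {
  with_seed(seed, {
    d <- round(rnorm(2, 0, jitter_px))
    scene2 <- translate_scene(scene, d[1], d[2])
    mpp <- scene$microns_per_pixel
    list(
      round1 = list(
        transmitted = render_channel(scene, "transmitted", noise, psf),
        tmrm = render_channel(scene, "TMRM", noise, psf),
        fitc = render_channel(scene, "FITC", noise, psf)),
      round2 = list(
        transmitted = render_channel(scene2, "transmitted", noise, psf),
        pi = render_channel(scene2, "PI", noise, psf),
        fda = render_kinetic_series(scene2, n_frames, dt, noise, psf)),
      registry = data.frame(
        round = c(1L, 2L), field_id = "f1",
        x_um = c(0, d[1] * mpp), y_um = c(0, d[2] * mpp),
        stringsAsFactors = FALSE),
      scene2 = scene2)
  })
}
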