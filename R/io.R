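## File exchange: 16-bit TIFF containers for the 14-bit images, CSV cell
## tables, YAML scene specs.

#' Read/write images as 16-bit TIFF
#'
#' Images are numeric matrices indexed (x, y) with values on the camera's
#' 14-bit scale; on disk they live in a 16-bit grayscale TIFF container.
#'
#' @param image numeric matrix
#' @param path file path
#' @return `read_image_tiff` returns the matrix; `write_image_tiff` the
#'   path, invisibly
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(t(image) / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  round(t(m) * 65535)
}

#' Write/read a ground-truth table
#'
#' @param scene a `field_scene`
#' @param path CSV path
#' @return the path (write) or the data.frame (read), invisibly/visibly
#' @export
write_ground_truth <- function(scene, path) {
  utils::write.csv(scene$cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Scene specification as YAML
#'
#' Persists the reproducible part of a scene (grid parameters, capacity,
#' optics, seed) so it can be regenerated; the cell table goes to CSV via
#' [write_ground_truth()].
#'
#' @param scene a `field_scene`
#' @param path YAML path
#' @export
write_scene_yaml <- function(scene, path) {
  spec <- list(
    pitch_um = scene$grid$pitch_um,
    microns_per_pixel = scene$microns_per_pixel,
    orientation = scene$grid$orientation,
    origin = as.numeric(scene$grid$origin),
    n_sites = nrow(scene$grid$sites),
    image_shape = as.integer(scene$image_shape),
    bit_depth = scene$bit_depth,
    capacity = scene$capacity,
    timepoint_h = scene$timepoint_h,
    seed = scene$seed,
    optics = scene$optics)
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Export a rendered scene to a directory
#'
#' Writes per-channel TIFFs, the ground-truth CSV and the scene YAML.
#'
#' @param scene a `field_scene`
#' @param dir output directory (created if needed)
#' @param channels channels to render and write
#' @param seed render seed
#' @return invisibly, the written paths
#' @export
export_scene <- function(scene, dir,
                         channels = c("transmitted", "TMRM", "FITC", "PI"),
                         seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ch in channels) {
    p <- file.path(dir, paste0(tolower(ch), ".tif"))
    write_image_tiff(render_channel(scene, ch, seed = seed), p)
    paths <- c(paths, p)
  }
  paths <- c(paths,
             write_ground_truth(scene, file.path(dir, "ground_truth.csv")),
             write_scene_yaml(scene, file.path(dir, "scene.yaml")))
  invisible(paths)
}
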