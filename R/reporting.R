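## Group-level statistics and the reproducible end-to-end run.

#' Percentage of dead (PI-positive) cells
#'
#' @param records cell table with logical `pi_positive`
#' @return percentage in 0..100
#' @examples
#' dead_fraction(data.frame(pi_positive = c(TRUE, FALSE, FALSE, FALSE)))
#' @export
dead_fraction <- function(records) {
  p <- records$pi_positive[!is.na(records$pi_positive)]
  if (length(p) == 0) param_error("empty population: no PI calls")
  100 * mean(p)
}

#' One-way ANOVA across replicate groups
#'
#' Classical one-way fixed-effects ANOVA on replicate-level values (the
#' replication unit is the field/device, not the cell, to avoid
#' pseudo-replication).
#'
#' @param groups named list of numeric vectors, one per group (>= 2 groups,
#'   each >= 2 values)
#' @return list: `F`, `p`, `p_2sig` (p to 2 significant figures), `df`
#' @examples
#' compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6)))$F
#' @export
compare_groups <- function(groups) {
  if (length(groups) < 2) param_error("need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2))
    param_error("each group needs >= 2 replicate values")
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups) %||% seq_along(groups),
                      vapply(groups, length, 0L)))
  gm <- tapply(value, group, mean)
  ssb <- sum(table(group) * (gm - mean(value))^2)
  sst <- sum((value - mean(value))^2)
  k <- nlevels(group); n <- length(value)
  df <- c(k - 1L, n - k)
  if (ssb <= 1e-12 * max(sst, .Machine$double.xmin))
    return(list(F = 0, p = 1, p_2sig = 1, df = df)) # identical group means
  an <- stats::anova(stats::lm(value ~ group))
  Fv <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  list(F = Fv, p = p, p_2sig = signif(p, 2), df = an$Df)
}

#' Per-group summary over fields
#'
#' @param field_records list of per-field cell tables belonging to one
#'   group (device/timepoint)
#' @param label group label
#' @return one-row data.frame: label, n_fields, n_cells, mean/SD of TMRM
#'   mean FI and FDA slope, dead and early-apoptotic percentages (mean over
#'   fields where available)
#' @export
group_summary <- function(field_records, label) {
  n_fields <- length(field_records)
  all <- do.call(rbind, field_records)
  pct_dead <- tryCatch(mean(vapply(field_records, dead_fraction, 0)),
                       error = function(e) NA_real_)
  data.frame(label = label, n_fields = n_fields, n_cells = nrow(all),
             tmrm_mean_fi = mean(all$tmrm_mean_fi, na.rm = TRUE),
             tmrm_mean_fi_sd = stats::sd(all$tmrm_mean_fi, na.rm = TRUE),
             fda_slope = mean(all$fda_slope, na.rm = TRUE),
             fda_slope_sd = stats::sd(all$fda_slope, na.rm = TRUE),
             pct_dead = pct_dead, stringsAsFactors = FALSE)
}

required_config_keys <- c("microns_per_pixel", "pitch_um", "n_cells",
                          "occupancy_mean", "seed", "out_dir")

validate_config <- function(config) {
  missing <- setdiff(required_config_keys, names(config))
  if (length(missing))
    config_error(paste0("run config is missing required key(s): ",
                        paste(missing, collapse = ", ")))
  invisible(config)
}

#' Run the full synthetic-to-report pipeline
#'
#' Simulate -> render two rounds -> detect grid -> quantify -> link ->
#' classify -> (optionally) proliferate -> write a report bundle: per-cell
#' CSV, subgroup-summary CSV, growth CSV, and a manifest recording the
#' configuration, seeds, package version and an md5 checksum for every
#' output file.
#'
#' @param config named list (or YAML file path) with at least
#'   `microns_per_pixel`, `pitch_um`, `n_cells`, `occupancy_mean`, `seed`,
#'   `out_dir`; optional `population` (one of "postthaw", "untreated",
#'   default "postthaw"), `growth = list(ratio_mean, ratio_sd,
#'   n_picowells)`
#' @return invisibly, list with `cells`, `summary`, `growth` (or NULL) and
#'   `manifest`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- switch(config$population %||% "postthaw",
                   postthaw = postthaw_subgroups(),
                   untreated = untreated_culture_subgroups(),
                   config_error("unknown population preset"))
  study <- run_multiparametric_study(
    params, n_cells = config$n_cells, seed = config$seed,
    occupancy_mean = config$occupancy_mean,
    microns_per_pixel = config$microns_per_pixel,
    pitch_um = config$pitch_um)

  cells_csv <- file.path(out_dir, "cells.csv")
  summary_csv <- file.path(out_dir, "subgroup_summary.csv")
  utils::write.csv(study$classified$records, cells_csv, row.names = FALSE)
  utils::write.csv(study$classified$summary, summary_csv, row.names = FALSE)
  files <- c(cells_csv, summary_csv)

  growth <- NULL
  if (!is.null(config$growth)) {
    g <- config$growth
    prol <- run_proliferation_study(
      n_picowells = g$n_picowells %||% 300,
      occupancy_mean = config$occupancy_mean,
      ratio_mean = g$ratio_mean %||% 1.26,
      ratio_sd = g$ratio_sd %||% 0.71,
      seed = config$seed + 100L,
      microns_per_pixel = config$microns_per_pixel,
      pitch_um = config$pitch_um)
    growth_csv <- file.path(out_dir, "growth.csv")
    utils::write.csv(prol$growth$records, growth_csv, row.names = FALSE)
    files <- c(files, growth_csv)
    growth <- prol$growth
  }

  manifest <- list(
    package = "picocyte",
    version = as.character(utils::packageVersion("picocyte")),
    config = config,
    seed = config$seed,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  manifest_json <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(cells = study$classified$records,
                 summary = study$classified$summary,
                 growth = growth, manifest = manifest))
}
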