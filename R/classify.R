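## Multi-parametric functional-status gating.
##
## Gate order follows the established Annexin V / PI assessment first, then
## the MMP split of the early-apoptotic (Annexin+/PI-) group: cells with no
## detectable TMRM signal form the MMP- subset, the rest the MMP+ subset,
## with the population-relative 30%-of-mean thresholds recorded on the gate
## path (the "low MMP and low slope" refinement).  Annexin-/PI+ cells fall
## outside the three canonical groups and are reported as a separate
## flagged class rather than forced into a gate.

CLASS_LEVELS <- c("live", "late_apoptotic", "early_apoptotic_MMP_pos",
                  "early_apoptotic_MMP_neg", "necrotic_unclassified",
                  "unclassifiable")

#' Population-relative gating thresholds
#'
#' The 30% thresholds are 0.30 times the arithmetic mean of the respective
#' per-cell measurement over the analyzed population (flagged/edge cells
#' excluded before calling this).
#'
#' @param records cell table with `tmrm_mean_fi` and `fda_slope`
#' @param tmrm_low_cut fixed low-MMP cut in au (population histogram
#'   convention)
#' @param tmrm_negative_cut TMRM detection floor in au; default 3 background
#'   SDs if `background_sd` is given, else 60
#' @param background_sd robust TMRM background SD
#' @return list of class `population_thresholds`: `mean_fi_30pct`,
#'   `slope_30pct`, `tmrm_low_cut`, `tmrm_negative_cut`
#' @examples
#' compute_thresholds(data.frame(tmrm_mean_fi = c(900, 1100),
#'                               fda_slope = c(30, 50)))
#' @export
compute_thresholds <- function(records, tmrm_low_cut = 200,
                               tmrm_negative_cut = NULL,
                               background_sd = NULL) {
  if (nrow(records) < 1) param_error("empty population")
  if (is.null(tmrm_negative_cut))
    tmrm_negative_cut <- if (!is.null(background_sd)) 3 * background_sd else 60
  structure(list(mean_fi_30pct = 0.30 * mean(records$tmrm_mean_fi,
                                             na.rm = TRUE),
                 slope_30pct = 0.30 * mean(records$fda_slope, na.rm = TRUE),
                 tmrm_low_cut = tmrm_low_cut,
                 tmrm_negative_cut = tmrm_negative_cut),
            class = "population_thresholds")
}

#' Classify cells by functional status
#'
#' Decision order per cell: (1) Annexin- and PI- is live; (2) Annexin+ and
#' PI+ is late apoptotic; (3) Annexin+ and PI- is early apoptotic, split
#' into MMP- (TMRM below the detection floor) and MMP+ (detectable TMRM),
#' the gate path recording whether the MMP+ cell is below both 30%
#' population thresholds ("MMP_low") or not ("MMP_not_low"); (4) Annexin-
#' and PI+ is flagged necrotic/unclassified.  Any missing measurement gives
#' `unclassifiable`, never a silent default.
#'
#' @param records cell table with `annexin_positive`, `pi_positive`,
#'   `tmrm_mean_fi`, `fda_slope`
#' @param thresholds a [compute_thresholds()] result
#' @return `records` with `class` (factor over live, late_apoptotic,
#'   early_apoptotic_MMP_pos, early_apoptotic_MMP_neg,
#'   necrotic_unclassified, unclassifiable) and `gate_path`
#' @export
classify_cells <- function(records, thresholds) {
  n <- nrow(records)
  lab <- character(n)
  path <- character(n)
  a <- records$annexin_positive
  p <- records$pi_positive
  tm <- records$tmrm_mean_fi
  sl <- records$fda_slope
  for (k in seq_len(n)) {
    if (is.na(a[k]) || is.na(p[k]) || is.na(tm[k]) || is.na(sl[k])) {
      lab[k] <- "unclassifiable"; path[k] <- "missing_measurement"
    } else if (!a[k] && !p[k]) {
      lab[k] <- "live"; path[k] <- "AnnV-/PI-"
    } else if (a[k] && p[k]) {
      lab[k] <- "late_apoptotic"; path[k] <- "AnnV+/PI+"
    } else if (a[k] && !p[k]) {
      if (tm[k] < thresholds$tmrm_negative_cut) {
        lab[k] <- "early_apoptotic_MMP_neg"
        path[k] <- "AnnV+/PI-;TMRM_negative"
      } else {
        low <- tm[k] < thresholds$mean_fi_30pct &&
          sl[k] < thresholds$slope_30pct
        lab[k] <- "early_apoptotic_MMP_pos"
        path[k] <- paste0("AnnV+/PI-;TMRM_detectable;",
                          if (low) "MMP_low" else "MMP_not_low")
      }
    } else {
      lab[k] <- "necrotic_unclassified"; path[k] <- "AnnV-/PI+"
    }
  }
  records$class <- factor(lab, levels = CLASS_LEVELS)
  records$gate_path <- path
  records
}

#' Subgroup summary table
#'
#' Percentage of the population and mean +/- SD of TMRM mean FI, TMRM FI SD
#' and FDA slope for each functional class.  Percentages are over all
#' classified records and sum to 100.
#'
#' @param records a [classify_cells()] result (columns `class`,
#'   `tmrm_mean_fi`, `tmrm_fi_sd`, `fda_slope`)
#' @return data.frame, one row per class: `class`, `n`, `pct`,
#'   `tmrm_mean_fi`, `tmrm_mean_fi_sd`, `tmrm_fi_sd`, `tmrm_fi_sd_sd`,
#'   `fda_slope`, `fda_slope_sd`
#' @export
summarize_population <- function(records) {
  if (!"class" %in% names(records))
    param_error("records must be classified first")
  total <- nrow(records)
  rows <- lapply(CLASS_LEVELS, function(cl) {
    r <- records[records$class == cl, , drop = FALSE]
    msd <- function(v) if (nrow(r)) c(mean(v), stats::sd(v)) else c(NA, NA)
    a <- msd(r$tmrm_mean_fi); b <- msd(r$tmrm_fi_sd); d <- msd(r$fda_slope)
    data.frame(class = cl, n = nrow(r),
               pct = if (total) 100 * nrow(r) / total else 0,
               tmrm_mean_fi = a[1], tmrm_mean_fi_sd = a[2],
               tmrm_fi_sd = b[1], tmrm_fi_sd_sd = b[2],
               fda_slope = d[1], fda_slope_sd = d[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
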