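## Subgroup parameter tables: the population mixtures the synthetic field
## generator draws from.  Each row is one functional subgroup with its
## mixture fraction, per-cell TMRM mean-FI distribution, within-cell FI-SD
## distribution, FDA hydrolysis slope distribution, and Annexin V / PI
## status.  All per-cell draws are normals truncated at 0 (the printed
## mean +/- SD values would otherwise produce negative intensities).

#' Build a subgroup-parameter table
#'
#' @param name character vector of subgroup labels
#' @param fraction mixture proportions; must sum to 1 within 1e-9
#' @param tmrm_mean_fi,tmrm_mean_fi_sd mean and SD (au) of the per-cell TMRM
#'   mean-FI distribution ("TMRM negative" subgroups use 0, 0)
#' @param tmrm_fi_sd,tmrm_fi_sd_sd mean and SD (au) of the per-cell
#'   within-cell FI-SD distribution
#' @param fda_slope,fda_slope_sd mean and SD (au/min) of the per-cell FDA
#'   hydrolysis slope distribution
#' @param annexin_positive,pi_positive logical staining status of the
#'   subgroup
#' @return data.frame of class `subgroup_params`
#' @examples
#' subgroup_params("live", 1, 250, 55, 170, 40, 60, 25, FALSE, FALSE)
#' @export
subgroup_params <- function(name, fraction,
                            tmrm_mean_fi, tmrm_mean_fi_sd,
                            tmrm_fi_sd, tmrm_fi_sd_sd,
                            fda_slope, fda_slope_sd,
                            annexin_positive, pi_positive) {
  p <- data.frame(name = name, fraction = fraction,
                  tmrm_mean_fi = tmrm_mean_fi,
                  tmrm_mean_fi_sd = tmrm_mean_fi_sd,
                  tmrm_fi_sd = tmrm_fi_sd, tmrm_fi_sd_sd = tmrm_fi_sd_sd,
                  fda_slope = fda_slope, fda_slope_sd = fda_slope_sd,
                  annexin_positive = annexin_positive,
                  pi_positive = pi_positive,
                  stringsAsFactors = FALSE)
  validate_subgroup_params(p)
  class(p) <- c("subgroup_params", "data.frame")
  p
}

validate_subgroup_params <- function(p) {
  if (nrow(p) < 1) param_error("at least one subgroup is required")
  if (any(p$fraction < 0) || abs(sum(p$fraction) - 1) > 1e-9)
    param_error("subgroup fractions must be non-negative and sum to 1")
  sds <- c(p$tmrm_mean_fi_sd, p$tmrm_fi_sd_sd, p$fda_slope_sd)
  if (any(sds < 0)) param_error("all SD parameters must be >= 0")
  if (anyDuplicated(p$name)) param_error("subgroup names must be unique")
  invisible(p)
}

#' Post-thaw U937 functional-status mixture
#'
#' Default four-subgroup mixture describing U937 cells 24 h after a slow
#' freeze / rapid thaw cycle: live (Annexin-/PI-), late-apoptotic
#' (Annexin+/PI+, TMRM and FDA negative), and the two early-apoptotic
#' (Annexin+/PI-) subsets split by whether mitochondrial TMRM signal is
#' detectable (MMP+) or absent (MMP-).  The printed percentages
#' 62/18/5/14 sum to 99; fractions are renormalised to sum to 1.
#'
#' @return `subgroup_params` table with rows live, late_apoptotic,
#'   early_apoptotic_MMP_pos, early_apoptotic_MMP_neg
#' @examples
#' postthaw_subgroups()
#' @export
postthaw_subgroups <- function() {
  subgroup_params(
    name = c("live", "late_apoptotic",
             "early_apoptotic_MMP_pos", "early_apoptotic_MMP_neg"),
    fraction = c(62, 18, 5, 14) / 99,
    tmrm_mean_fi    = c(1476, 0, 429, 0),
    tmrm_mean_fi_sd = c(331, 0, 131, 0),
    tmrm_fi_sd      = c(652, 0, 141, 0),
    tmrm_fi_sd_sd   = c(249, 0, 47, 0),
    fda_slope       = c(36.1, 0, 11, 9.05),
    fda_slope_sd    = c(11.36, 0, 7.1, 12.2),
    annexin_positive = c(FALSE, TRUE, TRUE, TRUE),
    pi_positive      = c(FALSE, TRUE, FALSE, FALSE))
}

#' Untreated U937 culture mixture
#'
#' Spontaneous-apoptosis composition of an untreated exponentially growing
#' U937 culture: 12% early apoptotic (of which 9 points of the total
#' population are MMP+ with considerable residual mitochondrial activity),
#' 5% late apoptotic, remainder live with the untreated TMRM population
#' statistics (mean FI 247.7 +/- 55.4 au, FI SD 172.2 +/- 41.5 au) and the
#' unfrozen FDA slope distribution (62.4 +/- 24.5 au/min).  MMP+ early
#' levels are not printed for untreated cultures; moderate levels
#' (150 +/- 50 au, slope 18 +/- 8 au/min) are used, chosen once as
#' plausible "considerable but reduced" activity.
#'
#' @return `subgroup_params` table
#' @export
untreated_culture_subgroups <- function() {
  subgroup_params(
    name = c("live", "late_apoptotic",
             "early_apoptotic_MMP_pos", "early_apoptotic_MMP_neg"),
    fraction = c(0.83, 0.05, 0.09, 0.03),
    tmrm_mean_fi    = c(247.7, 0, 150, 0),
    tmrm_mean_fi_sd = c(55.4, 0, 50, 0),
    tmrm_fi_sd      = c(172.2, 0, 90, 0),
    tmrm_fi_sd_sd   = c(41.5, 0, 30, 0),
    fda_slope       = c(62.4, 0, 18, 8),
    fda_slope_sd    = c(24.5, 0, 8, 10),
    annexin_positive = c(FALSE, TRUE, TRUE, TRUE),
    pi_positive      = c(FALSE, TRUE, FALSE, FALSE))
}

#' Single-subgroup populations for estimator round trips
#'
#' `untreated_tmrm_population()` is a pure population at the untreated TMRM
#' statistics (mean FI 247.7 +/- 55.4 au across cells, within-cell FI SD
#' 172.2 +/- 41.5 au); `unfrozen_fda_population()` a pure population at the
#' unfrozen FDA slope distribution (62.4 +/- 24.5 au/min).  Used to test
#' recovery of a single channel through the full render -> segment ->
#' measure path.
#'
#' @return `subgroup_params` table with a single `live` row
#' @export
untreated_tmrm_population <- function() {
  subgroup_params("live", 1, 247.7, 55.4, 172.2, 41.5, 62.4, 24.5,
                  FALSE, FALSE)
}

#' @rdname untreated_tmrm_population
#' @export
unfrozen_fda_population <- function() {
  subgroup_params("live", 1, 500, 100, 150, 40, 62.4, 24.5, FALSE, FALSE)
}
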