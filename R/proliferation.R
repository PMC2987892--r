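## Per-picowell proliferation tracking between time 0 and 48 h.

#' Count cells per picowell
#'
#' @param cell_records cell table with `picowell_id` (NA / edge cells are
#'   ignored); pass `edge` to drop field-edge picowells
#' @param roi_sites optional ROI site table ([build_roi_map()] `sites`) so
#'   empty picowells are reported with count 0; interior sites only
#' @return data.frame `picowell_id`, `count`
#' @export
count_per_picowell <- function(cell_records, roi_sites = NULL) {
  rec <- cell_records
  if ("edge" %in% names(rec)) rec <- rec[!rec$edge, , drop = FALSE]
  rec <- rec[!is.na(rec$picowell_id), , drop = FALSE]
  tab <- table(rec$picowell_id)
  ids <- if (!is.null(roi_sites)) {
    roi_sites$picowell_id[roi_sites$interior]
  } else names(tab)
  counts <- as.integer(tab[match(ids, names(tab))])
  counts[is.na(counts)] <- 0L
  data.frame(picowell_id = ids, count = counts, stringsAsFactors = FALSE)
}

#' Per-picowell growth ratios
#'
#' Ratio of the 48-h count to the time-0 count per picowell, with the
#' unweighted mean +/- SD of the ratios (matching the "average ratio"
#' convention) and the totals at both timepoints.  Picowells empty at time
#' 0 are excluded from the ratio summary and tallied; ones empty at time 0
#' but occupied at 48 h are additionally flagged as tracking anomalies.
#'
#' @param counts_t0,counts_t48 [count_per_picowell()] tables
#' @return list of class `growth_summary`: `records` (picowell_id,
#'   count_t0, count_t48, ratio), `mean_ratio`, `sd_ratio`, `n`,
#'   `total_t0`, `total_t48`, `n_empty_t0`, `anomalies`
#' @examples
#' g <- growth_ratios(data.frame(picowell_id = c("a", "b"), count = c(5, 10)),
#'                    data.frame(picowell_id = c("a", "b"), count = c(10, 5)))
#' g$mean_ratio
#' @export
growth_ratios <- function(counts_t0, counts_t48) {
  m <- merge(counts_t0, counts_t48, by = "picowell_id",
             suffixes = c("_t0", "_t48"))
  empty0 <- m$count_t0 == 0
  anomalies <- m$picowell_id[empty0 & m$count_t48 > 0]
  rec <- m[!empty0, , drop = FALSE]
  rec$ratio <- rec$count_t48 / rec$count_t0
  rownames(rec) <- NULL
  structure(list(records = rec,
                 mean_ratio = if (nrow(rec)) mean(rec$ratio) else NA_real_,
                 sd_ratio = if (nrow(rec) > 1) stats::sd(rec$ratio) else NA_real_,
                 n = nrow(rec),
                 total_t0 = sum(m$count_t0), total_t48 = sum(m$count_t48),
                 n_empty_t0 = sum(empty0),
                 anomalies = anomalies),
            class = "growth_summary")
}

#' @export
print.growth_summary <- function(x, ...) {
  cat(sprintf(
    "growth_summary: %d picowells, mean ratio %.3f +/- %.3f, totals %d -> %d\n",
    x$n, x$mean_ratio, x$sd_ratio, x$total_t0, x$total_t48))
  invisible(x)
}

#' Proliferating-picowell subset
#'
#' "An increase in cell number" is a ratio strictly greater than 1; the
#' complement ("no change or a decrease") is reported likewise.
#'
#' @param growth a [growth_ratios()] result
#' @return list: `proliferating` (fraction, n, mean_ratio, sd_ratio) and
#'   `non_proliferating` (same fields)
#' @examples
#' g <- growth_ratios(data.frame(picowell_id = letters[1:4], count = c(2, 1, 1, 1)),
#'                    data.frame(picowell_id = letters[1:4], count = c(1, 1, 2, 3)))
#' select_proliferating(g)$proliferating$fraction
#' @export
select_proliferating <- function(growth) {
  rec <- growth$records
  if (nrow(rec) == 0) param_error("no growth records")
  split_stats <- function(r) {
    list(fraction = nrow(r) / nrow(rec), n = nrow(r),
         mean_ratio = if (nrow(r)) mean(r$ratio) else NA_real_,
         sd_ratio = if (nrow(r) > 1) stats::sd(r$ratio) else NA_real_)
  }
  list(proliferating = split_stats(rec[rec$ratio > 1, , drop = FALSE]),
       non_proliferating = split_stats(rec[rec$ratio <= 1, , drop = FALSE]))
}
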