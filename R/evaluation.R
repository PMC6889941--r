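#' Window exclusion mask
#'
#' A window is excluded from agreement analysis when the estimator marked it
#' invalid (moving, lost features, no in-band peak), when the gold-standard
#' window is invalid, or when the gold-standard rate lies outside the
#' physiological validity range: 20-140 bpm for heart rate, 1-100 br/min for
#' respiratory rate.
#'
#' @param est,gold index-aligned [rate_series()] (identical window grids).
#' @param kind `"hr"` or `"rr"`.
#' @return data frame with `window_start_s`, `included` (logical) and
#'   `reason` (`"included"`, the estimator's reason, `"gold_invalid"` or
#'   `"gold_out_of_range"`).
#' @export
exclusion_mask <- function(est, gold, kind = c("hr", "rr")) {
  kind <- match.arg(kind)
  if (nrow(est) != nrow(gold) ||
      any(abs(est$window_start_s - gold$window_start_s) > 1e-9))
    stopf("estimate and gold-standard series are not on the same window grid")
  range_ok <- if (kind == "hr") c(20, 140) else c(1, 100)
  reason <- rep("included", nrow(est))
  reason[!gold$valid] <- "gold_invalid"
  reason[gold$valid & (gold$rate < range_ok[1] | gold$rate > range_ok[2])] <-
    "gold_out_of_range"
  reason[!est$valid] <- paste0("est_", est$reason[!est$valid])
  data.frame(window_start_s = est$window_start_s,
             included = reason == "included", reason = reason,
             stringsAsFactors = FALSE)
}

#' Agreement metrics between estimated and gold-standard rates
#'
#' Over the included windows: percent of estimates whose absolute error is at
#' most each threshold (closed bound), root mean square error and mean
#' absolute error. Default thresholds are 5 and 2.5 bpm for heart rate, 1 and
#' 0.5 br/min for breathing.
#'
#' @param est,gold index-aligned [rate_series()].
#' @param mask an [exclusion_mask()] result (or logical vector of inclusions).
#' @param thresholds numeric vector of error bounds.
#' @return list of class `agreement_report`: `pct_within` (named by
#'   threshold), `rmse`, `mae`, `n_windows_used`, `n_excluded_by_reason`.
#' @export
agreement_metrics <- function(est, gold, mask,
                              thresholds = c(5, 2.5)) {
  inc <- if (is.data.frame(mask)) mask$included else as.logical(mask)
  if (!any(inc)) stopf("no included windows: agreement metrics undefined")
  err <- est$rate[inc] - gold$rate[inc]
  pct <- vapply(thresholds, function(th) 100 * mean(abs(err) <= th), numeric(1))
  names(pct) <- as.character(thresholds)
  excl <- if (is.data.frame(mask)) {
    tab <- table(mask$reason[!mask$included])
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(sum(!inc), "excluded")
  structure(list(pct_within = pct,
                 rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                 n_windows_used = sum(inc), n_excluded_by_reason = excl),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d windows\n", x$n_windows_used))
  for (th in names(x$pct_within))
    cat(sprintf("  within %s: %.2f %%\n", th, x$pct_within[[th]]))
  cat(sprintf("  rmse = %.3f, mae = %.3f\n", x$rmse, x$mae))
  if (length(x$n_excluded_by_reason))
    cat("  excluded:", paste(names(x$n_excluded_by_reason),
                             x$n_excluded_by_reason, collapse = ", "), "\n")
  invisible(x)
}

#' Mean-hold baseline
#'
#' The do-nothing competitor: the mean gold-standard rate over the first
#' `hold_after_s` seconds (default 10 minutes), held constant for every
#' window after that point. Quantifies how much overnight rate variability
#' the pipeline actually captures.
#'
#' @param gold a [rate_series()] covering more than `hold_after_s`.
#' @param hold_after_s length of the averaging prefix, seconds.
#' @return A [rate_series()] on the post-prefix windows.
#' @export
mean_hold_baseline <- function(gold, hold_after_s = 600) {
  if (!nrow(gold) || max(gold$window_start_s) <= hold_after_s)
    stopf("recording must extend beyond %g s for the mean-hold baseline",
          hold_after_s)
  pre <- gold$valid & gold$window_start_s < hold_after_s
  if (!any(pre)) stopf("no valid gold windows in the first %g s", hold_after_s)
  m <- mean(gold$rate[pre])
  post <- gold$window_start_s >= hold_after_s
  rate_series(gold$window_start_s[post], rate = m, quality = NA_real_,
              valid = TRUE, reason = "ok")
}

#' Stratified agreement metrics
#'
#' Assigns each window to the annotation stratum containing its start time
#' and reports agreement metrics per stratum, per stratum type (e.g. sleep
#' stage, body position, coverage). Empty strata are omitted.
#'
#' @param est,gold index-aligned [rate_series()].
#' @param mask an [exclusion_mask()] result.
#' @param annotations data frame with `start_s`, `end_s`, `stratum_type`,
#'   `stratum_value`; intervals of one type must not overlap with
#'   contradictory values.
#' @param thresholds error bounds passed to [agreement_metrics()].
#' @return named list: `type` -> `value` -> `agreement_report`.
#' @export
stratified_metrics <- function(est, gold, mask, annotations,
                               thresholds = c(5, 2.5)) {
  stopifnot(all(c("start_s", "end_s", "stratum_type", "stratum_value")
                %in% names(annotations)))
  out <- list()
  for (ty in unique(annotations$stratum_type)) {
    ann <- annotations[annotations$stratum_type == ty, , drop = FALSE]
    assign_one <- function(t0) {
      hit <- which(ann$start_s <= t0 & t0 < ann$end_s)
      if (length(unique(ann$stratum_value[hit])) > 1L)
        stopf("contradictory '%s' annotations at t = %g s", ty, t0)
      if (length(hit)) ann$stratum_value[hit[1]] else NA_character_
    }
    stratum <- vapply(est$window_start_s, assign_one, character(1))
    reports <- list()
    for (v in unique(stratum[!is.na(stratum)])) {
      sel <- which(!is.na(stratum) & stratum == v)
      inc <- mask$included[sel]
      if (!any(inc)) next
      reports[[v]] <- agreement_metrics(est[sel, , drop = FALSE],
                                        gold[sel, , drop = FALSE],
                                        inc, thresholds)
    }
    out[[ty]] <- reports
  }
  out
}

#' Read an annotation table
#'
#' Delimited text with columns `start_s`, `end_s`, `stratum_type`,
#' `stratum_value`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return data frame.
#' @export
read_annotations <- function(path, sep = ",") {
  read.csv(path, sep = sep, stringsAsFactors = FALSE)
}
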