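# Quantile-based outlier screening of per-sample short-read repeat
# estimates, and PPV/sensitivity of the screen against confirmed repeat
# numbers from a reliable method (amplicon sequencing or fragment sizing).
# Short-read estimators underestimate the repeat count heavily; outlier
# status within a cohort, not the estimate itself, is the screening signal.

#' Flag repeat-size outliers above empirical quantiles
#'
#' Flags samples whose estimate is strictly greater than the q-th empirical
#' quantile of the cohort distribution (linear-interpolation quantile,
#' R type 7). Raising q never enlarges the flagged set.
#'
#' @param estimates Named numeric vector (names = sample ids) or data.frame
#'   with `sample_id` and `estimated_repeats`.
#' @param q Quantile levels (default `c(0.85, 0.90, 0.95, 0.99)`).
#' @param min_samples Minimum cohort size (default 20).
#' @return Named list (one element per quantile level) of flagged sample-id
#'   character vectors; quantile values attached as attribute `cutoffs`.
#' @export
quantile_flags <- function(estimates, q = c(0.85, 0.90, 0.95, 0.99),
                           min_samples = 20L) {
  if (is.data.frame(estimates)) {
    estimates <- stats::setNames(estimates$estimated_repeats,
                                 estimates$sample_id)
  }
  if (length(estimates) == 0L) stop("empty estimate table", call. = FALSE)
  if (is.null(names(estimates)) || any(!nzchar(names(estimates)))) {
    stop("estimates must be named by sample id", call. = FALSE)
  }
  if (length(estimates) < min_samples) {
    stop("need at least ", min_samples, " samples", call. = FALSE)
  }
  if (any(estimates < 0)) stop("estimates must be >= 0", call. = FALSE)
  stopifnot(all(q > 0), all(q < 1))
  cutoffs <- stats::quantile(estimates, q, type = 7, names = FALSE)
  flags <- lapply(cutoffs, function(cut) names(estimates)[estimates > cut])
  names(flags) <- sprintf("q%g", 100 * q)
  attr(flags, "cutoffs") <- stats::setNames(cutoffs, names(flags))
  flags
}

#' Evaluate a screening call set against confirmed repeat numbers
#'
#' `TP` = flagged samples confirmed at or above the threshold, `FP` =
#' flagged below it, `FN` = unflagged samples confirmed at or above it.
#' `PPV = TP / (TP + FP)` and `sensitivity = TP / (TP + FN)`; either is `NA`
#' when its denominator is zero. True negatives are not used by these
#' formulas and are not reported.
#'
#' @param flagged Character vector of flagged sample ids.
#' @param confirmed Named numeric vector of confirmed repeat numbers; must
#'   cover every flagged sample, and defines the population over which FN
#'   is counted.
#' @param threshold Repeat-number threshold (200, 250 or 300 in typical use).
#' @return List with `TP`, `FP`, `FN`, `PPV`, `sensitivity`.
#' @export
evaluate_screen <- function(flagged, confirmed, threshold) {
  missing_conf <- setdiff(flagged, names(confirmed))
  if (length(missing_conf) > 0L) {
    stop("flagged samples without confirmation value: ",
         paste(missing_conf, collapse = ", "), call. = FALSE)
  }
  is_flagged <- names(confirmed) %in% flagged
  pos <- confirmed >= threshold
  tp <- sum(is_flagged & pos)
  fp <- sum(is_flagged & !pos)
  fn <- sum(!is_flagged & pos)
  list(
    TP = tp, FP = fp, FN = fn,
    PPV = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  )
}
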