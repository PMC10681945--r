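#' Round half away from zero
#'
#' Commercial ("half-up") rounding, the convention used when reproducing
#' printed percentages (87.5 prints as 88, unlike banker's rounding). A
#' tiny epsilon absorbs floating-point representation error so that values
#' that are exactly half at full precision round up.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8 * pmax(1, abs(x) * p)) / p
}

#' Percent change between two printed means
#'
#' The percent increase `100*(to-from)/from` or decrease
#' `100*(from-to)/from`, rounded the way such changes are printed: half-up
#' to a whole percent, keeping one decimal when the magnitude is below 10.
#'
#' @param from Starting value; must be positive.
#' @param to Ending value.
#' @param mode `"increase"` or `"decrease"` (which direction is reported as
#'   positive).
#' @return The rounded signed percentage.
#' @export
#' @examples
#' percent_change(91.7, 34.9, "decrease")  # 62
#' percent_change(396, 776, "increase")    # 96
percent_change <- function(from, to, mode = c("increase", "decrease")) {
  mode <- match.arg(mode)
  if (any(from <= 0)) stop("percent change undefined for from <= 0",
                           call. = FALSE)
  v <- if (mode == "increase") 100 * (to - from) / from
       else 100 * (from - to) / from
  ifelse(abs(v) < 10, round_half_up(v, 1), round_half_up(v, 0))
}

#' Flag a meaningful modeled change
#'
#' Substitution modeling on the same subjects violates the independence
#' assumptions of ordinary tests, so scenario results are judged against a
#' fixed threshold instead: a change of at least 10% of the baseline mean
#' is considered meaningful.
#'
#' @param baseline_mean,adjusted_mean Group-level means.
#' @param threshold Meaningful-change threshold in percent.
#' @return A list: `percent` (unrounded signed percent change),
#'   `meaningful` (logical), `undefined` (`TRUE` when the baseline is zero,
#'   in which case `percent` and `meaningful` are `NA`).
#' @export
flag_meaningful_change <- function(baseline_mean, adjusted_mean,
                                   threshold = 10) {
  if (baseline_mean == 0) {
    return(list(percent = NA_real_, meaningful = NA, undefined = TRUE))
  }
  pct <- 100 * (adjusted_mean - baseline_mean) / baseline_mean
  list(percent = pct, meaningful = abs(pct) >= threshold, undefined = FALSE)
}
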