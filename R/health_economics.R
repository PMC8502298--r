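#' Incremental cost-effectiveness of one strategy against a comparator
#'
#' Computes the incremental cost, QALYs and life-years of `intervention`
#' over `comparator`, and the incremental cost-effectiveness ratio (ICER)
#' per QALY and per life-year. Standard dominance labels replace the ratio
#' when an increment is non-positive: `"dominant"` (cheaper and more
#' effective) and `"dominated"` (costlier and no more effective). Ratios are
#' formed from unrounded increments; rounding is left to report time.
#'
#' @param intervention,comparator `arm_outcome` objects from
#'   [accumulate_outcomes()] or [run_arm()], produced under identical
#'   simulation settings.
#' @return An `incremental_result` with `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `icer_per_qaly`, `icer_per_ly` (numeric, or the character
#'   dominance label).
#' @export
icer <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "arm_outcome"),
            inherits(comparator, "arm_outcome"))
  si <- intervention$settings; sc <- comparator$settings
  if (!identical(si[c("horizon_cycles", "annual_discount", "cohort_size")],
                 sc[c("horizon_cycles", "annual_discount", "cohort_size")])) {
    stop("arm outcomes were produced under different simulation settings",
         call. = FALSE)
  }
  dc <- intervention$cost_discounted - comparator$cost_discounted
  dq <- intervention$qaly_discounted - comparator$qaly_discounted
  dl <- intervention$ly_undiscounted - comparator$ly_undiscounted
  structure(
    list(delta_cost = dc,
         delta_qaly = dq,
         delta_ly = dl,
         icer_per_qaly = icer_ratio(dc, dq),
         icer_per_ly = icer_ratio(dc, dl),
         intervention = intervention$arm %||% "intervention",
         comparator = comparator$arm %||% "comparator"),
    class = "incremental_result"
  )
}

# Quadrant convention: ratio only when both increments are positive
# (NE quadrant); cheaper-and-better is dominant, costlier-and-no-better is
# dominated; cheaper-and-worse (SW) is reported as a ratio too, interpreted
# against the threshold from below.
icer_ratio <- function(delta_cost, delta_effect) {
  if (delta_effect > 0 && delta_cost < 0) return("dominant")
  if (delta_effect <= 0 && delta_cost > 0) return("dominated")
  if (delta_effect == 0 && delta_cost <= 0) return("dominant")
  delta_cost / delta_effect
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' `NMB = lambda * delta_QALY - delta_cost`. Positive NMB at threshold
#' `lambda` is equivalent to the strategy being cost-effective at that
#' willingness to pay.
#'
#' @param result An `incremental_result` from [icer()], or a list with
#'   `delta_cost` and `delta_qaly`.
#' @param wtp Willingness-to-pay threshold in US$ per QALY (>= 0); vectorized.
#' @return Net monetary benefit in US$.
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * result$delta_qaly - result$delta_cost
}

#' Willingness-to-pay tier decision for an incremental result
#'
#' Classifies a strategy by its ICER per QALY against a two-tier threshold:
#' `"very cost-effective"` when ICER <= the lower tier (1x GDP per capita;
#' US$25,000 in the Taiwan base case), `"cost-effective"` when <= the upper
#' tier (3x GDP; US$75,000), else `"not cost-effective"`. A dominant strategy
#' is always very cost-effective and a dominated one never is.
#'
#' @param result An `incremental_result` from [icer()].
#' @param thresholds Numeric vector of two increasing thresholds
#'   `c(very, upper)` in US$/QALY.
#' @return One of `"very cost-effective"`, `"cost-effective"`,
#'   `"not cost-effective"`.
#' @export
ce_decision <- function(result, thresholds = c(25000, 75000)) {
  stopifnot(length(thresholds) == 2, thresholds[1] <= thresholds[2],
            all(thresholds >= 0))
  r <- result$icer_per_qaly
  if (identical(r, "dominant")) return("very cost-effective")
  if (identical(r, "dominated")) return("not cost-effective")
  if (result$delta_qaly < 0) return("not cost-effective")
  if (r <= thresholds[1]) "very cost-effective"
  else if (r <= thresholds[2]) "cost-effective"
  else "not cost-effective"
}

#' @export
print.incremental_result <- function(x, ...) {
  fmt <- function(v) if (is.character(v)) v else sprintf("%.1f", v)
  cat(sprintf("<incremental_result: %s vs %s>\n", x$intervention, x$comparator))
  cat(sprintf("  delta cost  %12.2f US$\n", x$delta_cost))
  cat(sprintf("  delta QALY  %12.4f\n", x$delta_qaly))
  cat(sprintf("  delta LY    %12.4f\n", x$delta_ly))
  cat(sprintf("  ICER/QALY   %12s\n", fmt(x$icer_per_qaly)))
  cat(sprintf("  ICER/LY     %12s\n", fmt(x$icer_per_ly)))
  invisible(x)
}
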