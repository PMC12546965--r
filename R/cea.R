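# Incremental cost-effectiveness: ICER, net monetary benefit, dominance and
# willingness-to-pay classification for a two-strategy comparison.

#' Incremental cost-effectiveness ratio
#'
#' `(cost_a - cost_b) / (qaly_a - qaly_b)`, or `NA` when the QALY delta is
#' zero (undefined is a value here, not an error). The ratio is only
#' decision-meaningful when both deltas share a sign; dominance handling
#' lives in [classify_cea()].
#'
#' @param cost_a,qaly_a Cost and QALY of the intervention strategy.
#' @param cost_b,qaly_b Cost and QALY of the comparator.
#' @return USD per QALY, or `NA_real_`.
#' @export
icer <- function(cost_a, qaly_a, cost_b, qaly_b) {
  dq <- qaly_a - qaly_b
  if (dq == 0) return(NA_real_)
  (cost_a - cost_b) / dq
}

#' Classify an incremental result at a willingness-to-pay threshold
#'
#' \describe{
#'   \item{dominant}{cheaper and more effective.}
#'   \item{dominated}{more expensive and less effective ("inferior").}
#'   \item{cost_effective}{positive net monetary benefit at `wtp` (ties at
#'     zero resolve to cost-effective), without dominance.}
#'   \item{not_cost_effective}{negative net monetary benefit.}
#'   \item{indifferent}{both deltas exactly zero.}
#' }
#'
#' @param delta_cost Incremental cost (intervention minus comparator), USD.
#' @param delta_qaly Incremental QALYs.
#' @param wtp Willingness-to-pay threshold, USD/QALY (>= 0).
#' @return One of `"dominant"`, `"dominated"`, `"cost_effective"`,
#'   `"not_cost_effective"`, `"indifferent"`.
#' @export
#' @examples
#' classify_cea(1924, 0.008, wtp = 100000)  # not_cost_effective
classify_cea <- function(delta_cost, delta_qaly, wtp) {
  stopifnot(wtp >= 0)
  if (delta_cost == 0 && delta_qaly == 0) return("indifferent")
  if (delta_cost < 0 && delta_qaly > 0) return("dominant")
  if (delta_cost > 0 && delta_qaly < 0) return("dominated")
  if (nmb(delta_cost, delta_qaly, wtp) >= 0) "cost_effective" else "not_cost_effective"
}

#' Net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`; positive exactly when the intervention is
#' acceptable at that threshold (dominant results always have positive NMB).
#'
#' @inheritParams classify_cea
#' @return USD.
#' @export
nmb <- function(delta_cost, delta_qaly, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * delta_qaly - delta_cost
}

#' Compare two cohort traces
#'
#' Assembles the incremental result for an intervention/comparator pair of
#' [run_cohort()] traces: per-strategy cumulative cost and QALYs, deltas,
#' ICER, and the classification at the willingness-to-pay threshold.
#'
#' @param trace_int `cohort_trace` of the intervention (probiotic) arm.
#' @param trace_cmp `cohort_trace` of the comparator (no prophylaxis) arm.
#' @param wtp Willingness-to-pay threshold, USD/QALY; default 100000.
#' @return A `cea_result` list: `strategy_names`, `cost`, `qaly`,
#'   `delta_cost`, `delta_qaly`, `icer`, `nmb`, `classification`, `wtp`.
#' @export
#' @examples
#' ps <- load_defaults("primary")
#' arms <- build_primary(ps)
#' res <- cea_compare(run_cohort(arms$probiotic, ps, 2),
#'                    run_cohort(arms$no_prophylaxis, ps, 2))
#' res$icer
cea_compare <- function(trace_int, trace_cmp, wtp = 1e5) {
  dc <- trace_int$cumulative_cost - trace_cmp$cumulative_cost
  dq <- trace_int$cumulative_qaly - trace_cmp$cumulative_qaly
  structure(list(
    strategy_names = c(trace_int$strategy, trace_cmp$strategy),
    cost = c(trace_int$cumulative_cost, trace_cmp$cumulative_cost),
    qaly = c(trace_int$cumulative_qaly, trace_cmp$cumulative_qaly),
    delta_cost = dc, delta_qaly = dq,
    icer = icer(trace_int$cumulative_cost, trace_int$cumulative_qaly,
                trace_cmp$cumulative_cost, trace_cmp$cumulative_qaly),
    nmb = nmb(dc, dq, wtp),
    classification = classify_cea(dc, dq, wtp),
    wtp = wtp), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result: %s vs %s>\n", x$strategy_names[1], x$strategy_names[2]))
  cat(sprintf("  cost: $%.0f vs $%.0f (delta $%.0f)\n",
              x$cost[1], x$cost[2], x$delta_cost))
  cat(sprintf("  QALY: %.3f vs %.3f (delta %.5f)\n",
              x$qaly[1], x$qaly[2], x$delta_qaly))
  if (is.na(x$icer)) {
    cat("  ICER: undefined (zero QALY delta)\n")
  } else {
    cat(sprintf("  ICER: $%.0f/QALY\n", x$icer))
  }
  cat(sprintf("  at WTP $%.0f/QALY: %s (NMB $%.0f)\n",
              x$wtp, x$classification, x$nmb))
  invisible(x)
}
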