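# One-way deterministic sensitivity analysis: sweep a single parameter,
# recompute the full two-arm pipeline at each value, and locate the points
# where the willingness-to-pay classification changes.

# Accept either a builder function(ps) -> list(probiotic, no_prophylaxis)
# or a model keyword.
.resolve_builder <- function(model_builder) {
  if (is.function(model_builder)) return(model_builder)
  switch(match.arg(model_builder, c("primary", "secondary")),
         primary = function(ps) build_primary(ps, "base"),
         secondary = build_secondary)
}

.eval_point <- function(models, ps, wtp, horizon_years, discount_rate) {
  cea_compare(run_cohort(models$probiotic, ps, horizon_years, discount_rate),
              run_cohort(models$no_prophylaxis, ps, horizon_years, discount_rate),
              wtp = wtp)
}

.acceptable <- function(classification) {
  classification %in% c("dominant", "cost_effective")
}

#' One-way sensitivity sweep
#'
#' Evaluates the two-strategy comparison at `n_points` equally spaced values
#' of one parameter (all other parameters held at their values in `ps`) and
#' refines every classification change by bisection. Deterministic; sweep
#' values may exceed the parameter's Monte Carlo range but never its role
#' bounds.
#'
#' @param model_builder `"primary"`, `"secondary"`, or a function mapping a
#'   `parameter_set` to a `probiotic` / `no_prophylaxis` strategy pair.
#' @param ps Baseline `parameter_set`.
#' @param parameter Name of the swept parameter.
#' @param low,high Sweep range (`low < high`).
#' @param n_points Grid size (default 199).
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @param horizon_years,discount_rate Passed to [run_cohort()].
#' @param tol Bisection tolerance as a fraction of the sweep range
#'   (default 1e-4).
#' @return A `threshold_result`: `parameter`, `sweep_range`, `wtp`,
#'   `thresholds` (data.frame: `value`, `class_below`, `class_above`) and
#'   `curve` (data.frame: `value`, `icer`, `nmb`, `classification`).
#' @export
#' @examples
#' ps <- load_defaults("primary")
#' sw <- owsa_sweep("primary", ps, "cost_probiotic_2wk", 1, 150, n_points = 31)
#' sw$thresholds
owsa_sweep <- function(model_builder, ps, parameter, low, high,
                       n_points = 199, wtp = 1e5, horizon_years = 2,
                       discount_rate = 0.03, tol = 1e-4) {
  stopifnot(low < high, n_points >= 2)
  builder <- .resolve_builder(model_builder)
  models <- builder(ps)
  grid <- seq(low, high, length.out = n_points)
  res <- lapply(grid, function(v) {
    .eval_point(models, override(ps, parameter, v), wtp, horizon_years,
                discount_rate)
  })
  curve <- data.frame(
    value = grid,
    icer = vapply(res, function(r) r$icer, numeric(1)),
    nmb = vapply(res, function(r) r$nmb, numeric(1)),
    classification = vapply(res, function(r) r$classification, character(1)),
    stringsAsFactors = FALSE)

  thresholds <- data.frame(value = numeric(), class_below = character(),
                           class_above = character(), stringsAsFactors = FALSE)
  cls <- curve$classification
  cls_at <- function(v) {
    .eval_point(models, override(ps, parameter, v), wtp, horizon_years,
                discount_rate)$classification
  }
  for (i in which(cls[-1] != cls[-n_points])) {
    # refine the change inside its own grid interval, where the two
    # neighbouring classifications bracket a single boundary
    thr <- .bisect_classification(cls_at, grid[i], grid[i + 1], cls[i],
                                  tol * (high - low))
    thresholds <- rbind(thresholds,
                        data.frame(value = thr, class_below = cls[i],
                                   class_above = cls[i + 1],
                                   stringsAsFactors = FALSE))
  }
  structure(list(parameter = parameter, sweep_range = c(low, high), wtp = wtp,
                 thresholds = thresholds, curve = curve),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result: %s over [%g, %g] at WTP $%.0f>\n",
              x$parameter, x$sweep_range[1], x$sweep_range[2], x$wtp))
  if (nrow(x$thresholds) == 0) {
    cat("  no classification change in range\n")
  } else {
    print(x$thresholds)
  }
  invisible(x)
}

#' @export
as.data.frame.threshold_result <- function(x, ...) x$curve

# bisect "classification equals the one at lo" inside a bracket known to
# contain a single boundary
.bisect_classification <- function(cls_at, lo, hi, cls_lo, tol) {
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (identical(cls_at(mid), cls_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Locate the acceptability threshold of a parameter by bisection
#'
#' Bisects the acceptability indicator (classification `dominant` or
#' `cost_effective` versus not) inside a bracket whose endpoints disagree:
#' the returned value is the crossing point of zero net monetary benefit at
#' `wtp`, to within `tol`. A bracket with the same acceptability at both
#' endpoints raises an error; use [owsa_sweep()] to map all classification
#' boundaries (including dominance boundaries) across a range.
#'
#' @inheritParams owsa_sweep
#' @param bracket Length-2 numeric; acceptability must differ at the two
#'   endpoints.
#' @param tol Absolute tolerance on the parameter value.
#' @return The threshold value.
#' @export
#' @examples
#' ps <- load_defaults("secondary")
#' find_threshold("secondary", ps, "p_relapse_no_ppx_annual",
#'                bracket = c(0.3, 0.7))
find_threshold <- function(model_builder, ps, parameter, bracket, wtp = 1e5,
                           horizon_years = 2, discount_rate = 0.03,
                           tol = 1e-6) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  builder <- .resolve_builder(model_builder)
  models <- builder(ps)
  acc_at <- function(v) {
    .acceptable(.eval_point(models, override(ps, parameter, v), wtp,
                            horizon_years, discount_rate)$classification)
  }
  lo <- bracket[1]; hi <- bracket[2]
  acc_lo <- acc_at(lo)
  if (identical(acc_lo, acc_at(hi))) {
    stop(sprintf("no acceptability change for '%s' in [%g, %g]",
                 parameter, lo, hi), call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (identical(acc_at(mid), acc_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
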