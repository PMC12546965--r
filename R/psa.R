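# Probabilistic sensitivity analysis: independent triangular draws for every
# parameter with a Monte Carlo range, full two-arm cohort evaluation per
# draw, classification tallies and cost-effectiveness acceptability curves.

# Draw n parameter vectors. Assumes the RNG is already seeded. Parameters are
# sampled column-wise in registry order (part of the reproducibility
# contract); utility pairs violating no-pouchitis >= active-pouchitis are
# jointly resampled so no draw carries sign-inverted utilities.
.draw_parameter_matrix <- function(reg, n) {
  P <- nrow(reg)
  draws <- matrix(rep(reg$base, each = n), nrow = n,
                  dimnames = list(NULL, reg$name))
  varied <- which(reg$mc_max > reg$mc_min)
  for (j in varied) {
    draws[, reg$name[j]] <- qtri(stats::runif(n), reg$mc_min[j], reg$base[j],
                                 reg$mc_max[j])
  }
  u_no <- match("utility_no_pouchitis", reg$name)
  u_ac <- match("utility_active_pouchitis", reg$name)
  if (!is.na(u_no) && !is.na(u_ac)) {
    bad <- which(draws[, u_no] < draws[, u_ac])
    while (length(bad)) {
      draws[bad, u_no] <- qtri(stats::runif(length(bad)), reg$mc_min[u_no],
                               reg$base[u_no], reg$mc_max[u_no])
      draws[bad, u_ac] <- qtri(stats::runif(length(bad)), reg$mc_min[u_ac],
                               reg$base[u_ac], reg$mc_max[u_ac])
      bad <- bad[draws[bad, u_no] < draws[bad, u_ac]]
    }
  }
  draws
}

.with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  expr
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n_draws` second-order Monte Carlo iterations: every parameter with a
#' Monte Carlo range is drawn independently from its triangular distribution
#' (mode at the base-case value), the deterministic two-arm cohort pipeline
#' is evaluated, and the incremental result is classified at the reference
#' willingness-to-pay threshold. Fully reproducible given `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param model_builder `"primary"`, `"secondary"`, or a builder function as
#'   in [owsa_sweep()]; keywords also select the parameter registry scope.
#' @param ps Baseline `parameter_set`; defaults to the scope's base case.
#'   Parameters without a Monte Carlo range stay at their `ps` value.
#' @param n_draws Number of parameter draws (>= 1).
#' @param seed Integer seed for the draw stream.
#' @param wtp Reference willingness-to-pay threshold, USD/QALY.
#' @param horizon_years,discount_rate Passed to [run_cohort()].
#' @param registry Parameter registry supplying the Monte Carlo ranges;
#'   defaults to [param_registry()] for the scope. Supplying a registry with
#'   collapsed ranges (`mc_min == mc_max == base`) makes every draw reproduce
#'   the base case, which is useful for validation.
#' @return A `psa_result`: `n_draws`, `seed`, `wtp`, `draws` (data.frame with
#'   per-draw `delta_cost`, `delta_qaly`, `icer`, `classification`),
#'   `parameter_draws` (the sampled matrix), and `tallies` (classification
#'   proportions, summing to 1).
#' @export
#' @examples
#' psa <- run_psa("primary", n_draws = 50, seed = 1)
#' psa$tallies
run_psa <- function(model_builder, ps = NULL, n_draws = 1000, seed = 1,
                    wtp = 1e5, horizon_years = 2, discount_rate = 0.03,
                    registry = NULL) {
  stopifnot(n_draws >= 1)
  scope <- if (is.character(model_builder)) {
    match.arg(model_builder, c("primary", "secondary"))
  } else if (!is.null(ps)) ps$model else {
    stop("a baseline `ps` is required when `model_builder` is a function",
         call. = FALSE)
  }
  if (is.null(ps)) ps <- load_defaults(scope)
  reg <- if (is.null(registry)) param_registry(ps$model) else registry
  if (any(reg$mc_min > reg$mc_max)) {
    stop("invalid Monte Carlo range in registry (min > max)", call. = FALSE)
  }
  # keep user overrides for parameters that are not varied
  reg$base <- unname(ps$values[reg$name])
  bad <- reg$mc_max > reg$mc_min &
    (reg$base < reg$mc_min | reg$base > reg$mc_max)
  reg$mc_min[bad] <- pmin(reg$mc_min[bad], reg$base[bad])
  reg$mc_max[bad] <- pmax(reg$mc_max[bad], reg$base[bad])

  builder <- .resolve_builder(model_builder)
  models <- builder(ps)

  draws <- .with_preserved_rng({
    set.seed(seed)
    .draw_parameter_matrix(reg, n_draws)
  })

  dc <- dq <- ic <- numeric(n_draws)
  cls <- character(n_draws)
  ps_i <- ps
  ps_i$provenance <- "psa_draw"
  for (i in seq_len(n_draws)) {
    ps_i$values[colnames(draws)] <- draws[i, ]
    r <- .eval_point(models, ps_i, wtp, horizon_years, discount_rate)
    dc[i] <- r$delta_cost; dq[i] <- r$delta_qaly
    ic[i] <- r$icer; cls[i] <- r$classification
  }
  lev <- c("dominant", "cost_effective", "not_cost_effective", "dominated",
           "indifferent")
  tallies <- table(factor(cls, levels = lev)) / n_draws
  structure(list(n_draws = n_draws, seed = seed, wtp = wtp,
                 draws = data.frame(delta_cost = dc, delta_qaly = dq,
                                    icer = ic, classification = cls,
                                    stringsAsFactors = FALSE),
                 parameter_draws = draws,
                 tallies = c(tallies)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result: %d draws, seed %d, WTP $%.0f>\n",
              x$n_draws, x$seed, x$wtp))
  print(round(x$tallies, 4))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with positive
#' net monetary benefit (draws where the probiotic dominates are acceptable
#' at every threshold).
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Strictly increasing willingness-to-pay values; default
#'   $0 to $500,000 in $10,000 steps.
#' @return A `ceac_curve` data.frame with columns `wtp` and
#'   `acceptable_fraction`.
#' @export
#' @examples
#' psa <- run_psa("primary", n_draws = 50, seed = 1)
#' head(ceac(psa))
ceac <- function(psa, wtp_grid = seq(0, 5e5, by = 1e4)) {
  stopifnot(inherits(psa, "psa_result"), length(wtp_grid) >= 1,
            !is.unsorted(wtp_grid, strictly = TRUE))
  frac <- vapply(wtp_grid, function(w) {
    mean(nmb(psa$draws$delta_cost, psa$draws$delta_qaly, w) > 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, acceptable_fraction = frac),
            class = c("ceac_curve", "data.frame"))
}
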