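# Generic discrete-time Markov cohort engine.
#
# Conventions (documented in the methods vignette):
#   * state-membership rewards accrue for the whole cycle at the cycle-start
#     discount factor (no half-cycle correction by default; `half_cycle = TRUE`
#     switches membership rewards to the start/end occupancy average);
#   * one-time transition costs are charged on entry, discounted at the
#     destination cycle's start;
#   * annual probabilities are converted to per-cycle probabilities under a
#     constant hazard, so survival over k cycles is (1 - p_annual)^(k * cl).

#' Annual-to-cycle probability conversion
#'
#' Constant-hazard conversion: the per-cycle probability `v` satisfies
#' `(1 - v)^(1 / cycle_length_years) = 1 - p_annual`, so complementary
#' survival compounds exactly over integer years.
#'
#' @param p_annual Annual probability in [0, 1].
#' @param cycle_length_years Cycle length in years (> 0).
#' @return Per-cycle probability.
#' @export
#' @examples
#' to_cycle_probability(0.4, 1 / 26)
to_cycle_probability <- function(p_annual, cycle_length_years) {
  stopifnot(all(p_annual >= 0), all(p_annual <= 1), cycle_length_years > 0)
  1 - (1 - p_annual)^cycle_length_years
}

#' Discount factor at an annual rate
#'
#' @param elapsed_years Time since model start, years (>= 0).
#' @param rate_annual Annual discount rate (>= 0); the models default to 3%.
#' @return `(1 + rate_annual)^(-elapsed_years)`.
#' @export
discount_factor <- function(elapsed_years, rate_annual) {
  stopifnot(all(elapsed_years >= 0), rate_annual >= 0)
  (1 + rate_annual)^(-elapsed_years)
}

#' Construct a strategy model
#'
#' Container for one strategy's state space and reward structure, consumed by
#' [run_cohort()] and the microsimulation oracle. Most users obtain these from
#' [build_primary()] / [build_secondary()] rather than building them directly.
#'
#' @param name Strategy label.
#' @param state_ids Character vector of state identifiers (fixed order; the
#'   order is part of the reproducibility contract).
#' @param utility_ref Named character vector mapping each state to the
#'   parameter holding its annual utility.
#' @param state_cost_fn `function(ps)` returning the per-cycle cost vector by
#'   state (probiotic while on prophylaxis, biologic doses due that cycle).
#' @param trans_fn `function(cycle, ps)` returning the row-stochastic
#'   transition matrix for that cycle (cycles indexed from 0).
#' @param entry_cost_fn `function(ps)` returning a states x states matrix of
#'   one-time costs charged on each transition (workup, antibiotic courses).
#' @param init Initial occupancy vector (sums to 1).
#' @param cycle_length_years Cycle length in years.
#' @param tags Named list of state-id sets; each tag must be closed under the
#'   transition rule so "ever entered" incidence is well defined.
#' @param time_varying Logical; `FALSE` lets the engine evaluate `trans_fn`
#'   once and reuse the matrix.
#' @return A `strategy_model`.
#' @export
new_strategy_model <- function(name, state_ids, utility_ref, state_cost_fn,
                               trans_fn, entry_cost_fn, init,
                               cycle_length_years, tags = list(),
                               time_varying = FALSE) {
  stopifnot(length(init) == length(state_ids),
            abs(sum(init) - 1) < 1e-12,
            setequal(names(utility_ref), state_ids))
  structure(list(name = name, state_ids = state_ids,
                 utility_ref = utility_ref[state_ids],
                 state_cost_fn = state_cost_fn, trans_fn = trans_fn,
                 entry_cost_fn = entry_cost_fn, init = init,
                 cycle_length_years = cycle_length_years, tags = tags,
                 time_varying = time_varying),
            class = "strategy_model")
}

#' @export
print.strategy_model <- function(x, ...) {
  cat(sprintf("<strategy_model '%s': %d states, cycle %.4f y>\n",
              x$name, length(x$state_ids), x$cycle_length_years))
  invisible(x)
}

.check_stochastic <- function(M, cycle, state_ids) {
  bad_row <- which(abs(rowSums(M) - 1) > 1e-12)
  if (length(bad_row)) {
    stop(sprintf("non-stochastic transition matrix at cycle %d: row '%s' sums to %.15g",
                 cycle, state_ids[bad_row[1]], rowSums(M)[bad_row[1]]),
         call. = FALSE)
  }
  if (any(M < -1e-15) || any(M > 1 + 1e-15)) {
    bad <- which(M < -1e-15 | M > 1 + 1e-15, arr.ind = TRUE)[1, ]
    stop(sprintf("transition probability outside [0,1] at cycle %d: row '%s'",
                 cycle, state_ids[bad[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Run a Markov cohort
#'
#' Propagates the cohort through `horizon_years / cycle_length` cycles and
#' accrues discounted costs and QALYs under the engine's reward conventions.
#'
#' @param model A `strategy_model`.
#' @param ps A `parameter_set` valid for the model.
#' @param horizon_years Horizon; must be a whole number of cycles.
#' @param discount_rate Annual discount rate (default 0.03).
#' @param half_cycle If `TRUE`, membership rewards use the average of the
#'   cycle's start and end occupancy (a trapezoidal half-cycle correction);
#'   default `FALSE`.
#' @return A `cohort_trace`: occupancy matrix (cycles 0..n by state),
#'   discounted per-cycle cost and QALY vectors, their cumulative sums, and
#'   `event_incidence` (per tag, cumulative proportion ever entering the
#'   tagged set at each cycle boundary).
#' @export
#' @examples
#' ps <- load_defaults("primary")
#' arms <- build_primary(ps)
#' tr <- run_cohort(arms$no_prophylaxis, ps, horizon_years = 2)
#' tr$event_incidence$ever_pouchitis[[53]]  # 2-year cumulative incidence
run_cohort <- function(model, ps, horizon_years, discount_rate = 0.03,
                       half_cycle = FALSE) {
  stopifnot(inherits(model, "strategy_model"), horizon_years > 0)
  cl <- model$cycle_length_years
  n_cycles <- round(horizon_years / cl)
  if (n_cycles < 1 || abs(n_cycles - horizon_years / cl) > 1e-6) {
    stop("horizon_years must be a positive whole number of cycles", call. = FALSE)
  }
  S <- length(model$state_ids)
  util <- unname(ps$values[model$utility_ref])
  if (anyNA(util)) stop("parameter set lacks a state utility", call. = FALSE)
  state_cost <- model$state_cost_fn(ps)
  entry <- model$entry_cost_fn(ps)
  stopifnot(length(state_cost) == S, all(dim(entry) == c(S, S)))

  M <- NULL
  if (!model$time_varying) {
    M <- model$trans_fn(0L, ps)
    .check_stochastic(M, 0L, model$state_ids)
  }

  occ <- matrix(0, n_cycles + 1L, S,
                dimnames = list(cycle = 0:n_cycles, state = model$state_ids))
  occ[1L, ] <- model$init
  cost <- qaly <- numeric(n_cycles)
  tag_names <- names(model$tags)
  tag_idx <- lapply(model$tags, function(s) match(s, model$state_ids))
  inc <- lapply(tag_idx, function(ix) {
    v <- numeric(n_cycles + 1L); v[1L] <- sum(model$init[ix]); v
  })
  names(inc) <- tag_names

  disc <- discount_factor((0:n_cycles) * cl, discount_rate)
  has_entry <- any(entry != 0)
  for (k in seq_len(n_cycles)) {        # cycle index k-1 (0-based)
    x <- occ[k, ]
    Mk <- if (model$time_varying) {
      m <- model$trans_fn(k - 1L, ps); .check_stochastic(m, k - 1L, model$state_ids); m
    } else M
    flows <- x * Mk                      # flows[i, j] = x[i] * M[i, j]
    x_next <- colSums(flows)
    occ[k + 1L, ] <- x_next
    xw <- if (half_cycle) (x + x_next) / 2 else x
    cost[k] <- sum(xw * state_cost) * disc[k]
    if (has_entry) cost[k] <- cost[k] + sum(flows * entry) * disc[k + 1L]
    qaly[k] <- sum(xw * util) * cl * disc[k]
    for (t in tag_names) {
      ix <- tag_idx[[t]]
      inc[[t]][k + 1L] <- inc[[t]][k] + sum(flows[-ix, ix, drop = FALSE])
    }
  }

  structure(list(occupancy = occ, per_cycle_cost = cost, per_cycle_qaly = qaly,
                 cumulative_cost = sum(cost), cumulative_qaly = sum(qaly),
                 event_incidence = inc, n_cycles = n_cycles,
                 cycle_length_years = cl, discount_rate = discount_rate,
                 half_cycle = half_cycle, strategy = model$name),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace '%s': %d cycles of %.4f y>\n", x$strategy,
              x$n_cycles, x$cycle_length_years))
  cat(sprintf("  cumulative discounted cost: $%.2f\n", x$cumulative_cost))
  cat(sprintf("  cumulative discounted QALY: %.4f\n", x$cumulative_qaly))
  for (t in names(x$event_incidence)) {
    cat(sprintf("  %s at horizon: %.4f\n", t,
                x$event_incidence[[t]][x$n_cycles + 1L]))
  }
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  df <- data.frame(cycle = 0:x$n_cycles, x$occupancy, check.names = FALSE)
  df$disc_cost <- c(x$per_cycle_cost, NA_real_)
  df$disc_qaly <- c(x$per_cycle_qaly, NA_real_)
  df
}

#' Export a cohort trace to CSV
#'
#' One row per cycle: occupancy by state plus the cycle's discounted cost and
#' QALY accrual (NA on the terminal boundary row, which accrues no rewards).
#'
#' @param trace A `cohort_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
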