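# Patient-level microsimulation oracle. Simulates individual trajectories
# under the same transition rules and reward conventions as the cohort
# engine, for validating the engine by aggregation and for generating
# synthetic parameter sets in tests.
#
# Reproducibility: all of a patient's transition uniforms are drawn up front
# as one (patients x cycles) matrix from the master seed, so patient i's
# stream does not depend on the order in which patients are evaluated.

.microsim_engine <- function(model, ps, n, seed, horizon_years,
                             discount_rate = 0.03, keep_histories = FALSE) {
  cl <- model$cycle_length_years
  n_cycles <- round(horizon_years / cl)
  stopifnot(n_cycles >= 1, abs(n_cycles - horizon_years / cl) < 1e-6)
  S <- length(model$state_ids)
  util <- unname(ps$values[model$utility_ref])
  state_cost <- model$state_cost_fn(ps)
  entry <- model$entry_cost_fn(ps)
  disc <- discount_factor((0:n_cycles) * cl, discount_rate)

  M <- model$trans_fn(0L, ps)
  .check_stochastic(M, 0L, model$state_ids)
  cum <- t(apply(M, 1, cumsum))

  draw <- .with_preserved_rng({
    set.seed(seed)
    list(u0 = stats::runif(n), u = matrix(stats::runif(n * n_cycles), n, n_cycles))
  })
  st <- findInterval(draw$u0, cumsum(model$init)) + 1L
  st <- pmin(st, S)

  occ_count <- matrix(0L, n_cycles + 1L, S,
                      dimnames = list(cycle = 0:n_cycles, state = model$state_ids))
  cost_acc <- qaly_acc <- numeric(n)
  tag_idx <- lapply(model$tags, function(s) match(s, model$state_ids))
  ever <- matrix(FALSE, n, length(tag_idx), dimnames = list(NULL, names(model$tags)))
  inc <- matrix(0, n_cycles + 1L, length(tag_idx),
                dimnames = list(cycle = 0:n_cycles, tag = names(model$tags)))
  states_hist <- if (keep_histories) matrix(0L, n, n_cycles + 1L) else NULL

  tab <- tabulate(st, nbins = S)
  occ_count[1L, ] <- tab
  for (t in seq_along(tag_idx)) ever[, t] <- st %in% tag_idx[[t]]
  inc[1L, ] <- colSums(ever)
  if (keep_histories) states_hist[, 1L] <- st

  Mk <- M; cumk <- cum
  for (k in seq_len(n_cycles)) {           # transition from cycle k-1 to k
    if (model$time_varying) {
      Mk <- model$trans_fn(k - 1L, ps)
      .check_stochastic(Mk, k - 1L, model$state_ids)
      cumk <- t(apply(Mk, 1, cumsum))
    }
    cost_acc <- cost_acc + state_cost[st] * disc[k]
    qaly_acc <- qaly_acc + util[st] * cl * disc[k]
    uk <- draw$u[, k]
    nxt <- integer(n)
    for (s in unique(st)) {
      idx <- which(st == s)
      nxt[idx] <- findInterval(uk[idx], cumk[s, ]) + 1L
    }
    nxt <- pmin(nxt, S)
    cost_acc <- cost_acc + entry[cbind(st, nxt)] * disc[k + 1L]
    st <- nxt
    occ_count[k + 1L, ] <- tabulate(st, nbins = S)
    for (t in seq_along(tag_idx)) ever[, t] <- ever[, t] | (st %in% tag_idx[[t]])
    inc[k + 1L, ] <- colSums(ever)
    if (keep_histories) states_hist[, k + 1L] <- st
  }

  list(n = n, n_cycles = n_cycles, cost = cost_acc, qaly = qaly_acc,
       occupancy = occ_count / n, event_incidence = inc / n,
       states = states_hist, disc = disc, cl = cl)
}

#' Simulate a single patient trajectory
#'
#' Draws one trajectory under the strategy's transition rule, accruing
#' discounted cost and QALYs with exactly the cohort engine's reward
#' conventions (cycle-start discounting, entry costs at the destination
#' cycle).
#'
#' @param model A `strategy_model`.
#' @param ps A `parameter_set`.
#' @param horizon_years Horizon (whole number of cycles).
#' @param seed Integer seed; the same seed reproduces the same history.
#' @param discount_rate Annual discount rate.
#' @return A `patient_history`: `strategy`, `states` (one id per cycle
#'   boundary, 0..n), `events` (data.frame of first entry cycles per tag),
#'   `accrued_cost`, `accrued_qaly`.
#' @export
#' @examples
#' ps <- load_defaults("primary")
#' arms <- build_primary(ps)
#' simulate_patient(arms$no_prophylaxis, ps, 2, seed = 7)
simulate_patient <- function(model, ps, horizon_years, seed,
                             discount_rate = 0.03) {
  sim <- .microsim_engine(model, ps, 1L, seed, horizon_years, discount_rate,
                          keep_histories = TRUE)
  states <- model$state_ids[sim$states[1L, ]]
  events <- do.call(rbind, lapply(names(model$tags), function(t) {
    hit <- which(states %in% model$tags[[t]])
    if (!length(hit)) return(NULL)
    data.frame(cycle = hit[1] - 1L, event = t, stringsAsFactors = FALSE)
  }))
  if (is.null(events)) {
    events <- data.frame(cycle = integer(), event = character(),
                         stringsAsFactors = FALSE)
  }
  structure(list(strategy = model$name, states = states, events = events,
                 accrued_cost = sim$cost[1L], accrued_qaly = sim$qaly[1L]),
            class = "patient_history")
}

#' @export
print.patient_history <- function(x, ...) {
  cat(sprintf("<patient_history '%s': %d cycles, cost $%.2f, QALY %.4f>\n",
              x$strategy, length(x$states) - 1L, x$accrued_cost, x$accrued_qaly))
  invisible(x)
}

#' Estimate cohort quantities by microsimulation
#'
#' Simulates `n` independent patients and aggregates them into empirical
#' occupancy, event incidence and mean discounted cost/QALY with standard
#' errors -- a consistent brute-force estimator of [run_cohort()].
#'
#' @inheritParams simulate_patient
#' @param n Number of patients (>= 2 for standard errors).
#' @return List with `n`, `mean_cost`, `se_cost`, `mean_qaly`, `se_qaly`,
#'   `occupancy` (empirical proportions, cycles 0..n by state),
#'   `occupancy_se`, and `event_incidence` (per tag).
#' @export
estimate_by_simulation <- function(model, ps, n, seed, horizon_years,
                                   discount_rate = 0.03) {
  stopifnot(n >= 2)
  sim <- .microsim_engine(model, ps, n, seed, horizon_years, discount_rate)
  list(n = n,
       mean_cost = mean(sim$cost), se_cost = stats::sd(sim$cost) / sqrt(n),
       mean_qaly = mean(sim$qaly), se_qaly = stats::sd(sim$qaly) / sqrt(n),
       occupancy = sim$occupancy,
       occupancy_se = sqrt(sim$occupancy * (1 - sim$occupancy) / n),
       event_incidence = sim$event_incidence)
}

#' Check cohort-trace / microsimulation agreement
#'
#' Runs the cohort engine and an `n_patients` microsimulation side by side
#' and reports occupancy differences in units of binomial Monte Carlo
#' standard errors (computed from the cohort probabilities), plus cost/QALY
#' mean differences with their standard errors. With `n_patients = 1`
#' standard errors are undefined and reported as `NA`.
#'
#' @inheritParams simulate_patient
#' @param n_patients Number of simulated patients.
#' @return List with `max_abs_occ_diff`, `max_occ_z` (max |difference| / SE
#'   over state-by-cycle cells with nonzero SE), `cost_diff`, `cost_se`,
#'   `qaly_diff`, `qaly_se`, and the two occupancy matrices.
#' @export
#' @examples
#' ps <- load_defaults("primary")
#' arms <- build_primary(ps)
#' chk <- microsim_equivalence_check(arms$probiotic, ps, 2000, seed = 1,
#'                                   horizon_years = 2)
#' chk$max_occ_z
microsim_equivalence_check <- function(model, ps, n_patients, seed,
                                       horizon_years, discount_rate = 0.03) {
  stopifnot(n_patients >= 1)
  trace <- run_cohort(model, ps, horizon_years, discount_rate)
  sim <- .microsim_engine(model, ps, n_patients, seed, horizon_years,
                          discount_rate)
  p <- trace$occupancy
  diff <- sim$occupancy - p
  se <- sqrt(p * (1 - p) / n_patients)
  z <- abs(diff) / ifelse(se > 0, se, NA_real_)
  list(n_patients = n_patients,
       max_abs_occ_diff = max(abs(diff)),
       max_occ_z = if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE),
       cost_diff = mean(sim$cost) - trace$cumulative_cost,
       cost_se = if (n_patients > 1) stats::sd(sim$cost) / sqrt(n_patients) else NA_real_,
       qaly_diff = mean(sim$qaly) - trace$cumulative_qaly,
       qaly_se = if (n_patients > 1) stats::sd(sim$qaly) / sqrt(n_patients) else NA_real_,
       cohort_occupancy = p, microsim_occupancy = sim$occupancy)
}

#' Generate synthetic parameter sets
#'
#' Draws `n` valid parameter sets from the registry's triangular
#' distributions (the PSA sampler), for property-style tests and synthetic
#' pipelines.
#'
#' @param model Registry scope, as in [load_defaults()].
#' @param n Number of sets (>= 1).
#' @param seed Integer seed.
#' @param registry Optional registry override, as in [run_psa()].
#' @return List of `parameter_set`s with `provenance = "psa_draw"`.
#' @export
#' @examples
#' sets <- generate_test_parameters("primary", 3, seed = 42)
#' validate_parameters(sets[[1]])
generate_test_parameters <- function(model, n, seed, registry = NULL) {
  stopifnot(n >= 1)
  reg <- if (!is.null(registry)) registry else
    param_registry(if (is.character(model)) model else model$model)
  draws <- .with_preserved_rng({
    set.seed(seed)
    .draw_parameter_matrix(reg, n)
  })
  base <- load_defaults(if (is.character(model)) model else model$model)
  lapply(seq_len(n), function(i) {
    out <- base
    out$values[colnames(draws)] <- draws[i, ]
    out$provenance <- "psa_draw"
    out$seed_info <- seed
    out
  })
}

#' Export patient histories to CSV
#'
#' Simulates `n` patients and writes one row per patient-cycle: patient id,
#' cycle, state, and the cycle's discounted cost and QALY accruals.
#'
#' @inheritParams estimate_by_simulation
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_histories_csv <- function(model, ps, n, seed, horizon_years, path,
                                discount_rate = 0.03) {
  sim <- .microsim_engine(model, ps, n, seed, horizon_years, discount_rate,
                          keep_histories = TRUE)
  state_cost <- model$state_cost_fn(ps)
  util <- unname(ps$values[model$utility_ref])
  rows <- lapply(seq_len(n), function(i) {
    stv <- sim$states[i, ]
    k <- 0:sim$n_cycles
    data.frame(patient = i, cycle = k, state = model$state_ids[stv],
               disc_cost = c(state_cost[stv[-length(stv)]] * sim$disc[-length(k)], NA),
               disc_qaly = c(util[stv[-length(stv)]] * sim$cl * sim$disc[-length(k)], NA))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
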