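# Cohort engine: probability conversion, discounting, reward accrual,
# conservation and limit behaviour.

test_that("annual-to-cycle conversion preserves compound survival", {
  expect_equal(to_cycle_probability(0, 1 / 26), 0)
  expect_equal(to_cycle_probability(1, 1 / 26), 1)
  v <- to_cycle_probability(0.1, 1 / 26)
  expect_equal((1 - v)^26, 0.9, tolerance = 1e-12)
  # two-year cumulative incidence at annual 0.4 is 1 - 0.6^2 = 64%
  v2 <- to_cycle_probability(0.4, 1 / 26)
  expect_equal(1 - (1 - v2)^52, 0.64, tolerance = 1e-12)
})

test_that("discount factors follow the closed form", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(2, 0), 1)
  expect_true(all(diff(discount_factor(0:10, 0.03)) < 0))
})

test_that("occupancy rows conserve mass across generated parameter sets", {
  for (scope in c("primary", "secondary")) {
    sets <- generate_test_parameters(scope, 5, seed = 202)
    build <- if (scope == "primary") function(p) build_primary(p) else build_secondary
    for (ps in sets) {
      arms <- build(ps)
      for (m in arms) {
        tr <- run_cohort(m, ps, 2)
        expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-10)
        expect_true(all(tr$occupancy >= -1e-15))
        # cumulative values are the sums of their per-cycle vectors
        expect_equal(tr$cumulative_cost, sum(tr$per_cycle_cost))
        expect_equal(tr$cumulative_qaly, sum(tr$per_cycle_qaly))
        # event incidence non-decreasing within [0, 1]
        for (inc in tr$event_incidence) {
          expect_true(all(diff(inc) >= -1e-12))
          expect_true(all(inc >= -1e-12 & inc <= 1 + 1e-12))
        }
      }
    }
  }
})

test_that("cumulative cost and QALY are non-increasing in the discount rate", {
  for (m in arms_primary) {
    runs <- lapply(c(0, 0.03, 0.1), function(r)
      run_cohort(m, base_primary, 2, discount_rate = r))
    costs <- vapply(runs, function(x) x$cumulative_cost, numeric(1))
    qalys <- vapply(runs, function(x) x$cumulative_qaly, numeric(1))
    expect_true(all(diff(costs) < 0))
    expect_true(all(diff(qalys) < 0))
  }
})

test_that("QALYs never exceed full health over discounted person-time", {
  for (m in c(arms_primary, arms_secondary)) {
    ps <- if (grepl("primary", m$name)) base_primary else base_secondary
    tr <- run_cohort(m, ps, 2)
    bound <- max(ps$values[c("utility_no_pouchitis", "utility_active_pouchitis")]) *
      tr$cycle_length_years * disc_sum(tr$n_cycles, tr$cycle_length_years)
    expect_lte(tr$cumulative_qaly, bound + 1e-12)
  }
})

test_that("with no events the arms reduce to closed-form accruals", {
  quiet <- override(base_primary, "p_first_pouchitis_no_ppx_annual", 0)
  quiet <- override(quiet, "p_first_pouchitis_ppx_annual", 0)
  arms <- build_primary(quiet)
  tn <- run_cohort(arms$no_prophylaxis, quiet, 2)
  tp <- run_cohort(arms$probiotic, quiet, 2)
  # no prophylaxis: zero cost, utility x discounted person-time
  expect_equal(tn$cumulative_cost, 0)
  expect_equal(tn$cumulative_qaly, 0.91 * (1 / 26) * disc_sum(52, 1 / 26),
               tolerance = 1e-12)
  # probiotic arm: the full discounted probiotic stream, nothing else
  expect_equal(tp$cumulative_cost, 87.2 * disc_sum(52, 1 / 26),
               tolerance = 1e-12)
  expect_equal(tp$cumulative_qaly, tn$cumulative_qaly)
})

test_that("a non-stochastic transition rule raises an error naming the row", {
  broken <- new_strategy_model(
    name = "broken", state_ids = c("a", "b"),
    utility_ref = c(a = "utility_no_pouchitis", b = "utility_no_pouchitis"),
    state_cost_fn = function(ps) c(0, 0),
    trans_fn = function(cycle, ps)
      matrix(c(0.5, 0.4, 0, 1), 2, 2, byrow = TRUE,
             dimnames = list(c("a", "b"), c("a", "b"))),
    entry_cost_fn = function(ps) matrix(0, 2, 2),
    init = c(1, 0), cycle_length_years = 1 / 26)
  expect_error(run_cohort(broken, base_primary, 2), "non-stochastic.*'a'")
})

test_that("the half-cycle switch changes accrual in the expected direction", {
  tr0 <- run_cohort(arms_primary$probiotic, base_primary, 2)
  tr1 <- run_cohort(arms_primary$probiotic, base_primary, 2, half_cycle = TRUE)
  # occupancy and incidence identical; only reward weighting differs
  expect_identical(tr0$occupancy, tr1$occupancy)
  # probiotic cost falls under averaging because the pouchitis-free pool shrinks
  expect_lt(tr1$cumulative_cost, tr0$cumulative_cost)
})

test_that("horizon must be a whole number of cycles", {
  expect_error(run_cohort(arms_primary$probiotic, base_primary, 2.01),
               "whole number of cycles")
})

test_that("traces export to CSV round-trip", {
  tr <- run_cohort(arms_secondary$probiotic, base_secondary, 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  got <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(got), tr$n_cycles + 1)
  expect_equal(got$rem0, unname(tr$occupancy[, "rem0"]))
  expect_equal(sum(got$disc_cost, na.rm = TRUE), tr$cumulative_cost,
               tolerance = 1e-9)
})
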