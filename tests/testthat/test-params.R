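# Parameter registry: tabulated values, overrides, triangular sampler.

test_that("registry holds every tabulated base value and Monte Carlo range", {
  # primary prevention inputs: (name, base, mc_min, mc_max)
  primary_expected <- list(
    list("p_first_pouchitis_ppx_annual",    0.10, 0.05, 0.25),
    list("p_first_pouchitis_no_ppx_annual", 0.40, 0.25, 0.50),
    list("p_recurrent_pouchitis_annual",    0.39, 0.20, 0.50),
    list("p_resp_cipro",                    0.77, 0.60, 0.95),
    list("p_resp_metro",                    0.70, 0.55, 0.90),
    list("cost_probiotic_2wk",              87.2,   50,  150),
    list("cost_cipro_2wk",                    12,    6,   24),
    list("cost_metro_2wk",                 22.68,   11,   45),
    list("cost_dual_4wk",                    270,  140,  500),
    list("cost_first_episode_workup",      612.6,  300, 1000),
    list("utility_no_pouchitis",            0.91, 0.70, 0.95),
    list("utility_active_pouchitis",        0.46, 0.30, 0.60))
  secondary_expected <- list(
    list("p_relapse_ppx_annual",            0.14, 0.10, 0.50),
    list("p_relapse_no_ppx_annual",         0.39, 0.25, 0.55),
    list("p_resp_cipro",                    0.77, 0.50, 0.90),
    list("p_resp_metro",                    0.70, 0.50, 0.90),
    list("p_resp_dual",                     0.69, 0.50, 0.90),
    list("p_resp_vdz",                      0.52, 0.30, 0.70),
    list("p_resp_ifx",                      1.00, 1.00, 1.00),
    list("p_lor_vdz_annual",                0.40, 0.20, 0.60),
    list("cost_probiotic_4wk",               174,  100,  300),
    list("cost_cipro_4wk",                    24,   12,   48),
    list("cost_metro_4wk",                  45.4,   25,   80),
    list("cost_dual_4wk",                    270,  150,  500),
    list("cost_vdz_dose",                   6803, 3500, 10000),
    list("cost_ifx_dose",                    987,  500, 1500),
    list("cost_carp_eval",                 128.4,   70,  200),
    list("utility_no_pouchitis",            0.91, 0.70, 0.95),
    list("utility_active_pouchitis",        0.46, 0.30, 0.60))
  for (scope in c("primary", "secondary")) {
    reg <- param_registry(scope)
    expected <- if (scope == "primary") primary_expected else secondary_expected
    for (e in expected) {
      i <- match(e[[1]], reg$name)
      expect_false(is.na(i), info = paste(scope, e[[1]]))
      expect_equal(reg$base[i], e[[2]], info = paste(scope, e[[1]]))
      expect_equal(reg$mc_min[i], e[[3]], info = paste(scope, e[[1]]))
      expect_equal(reg$mc_max[i], e[[4]], info = paste(scope, e[[1]]))
    }
  }
  reg <- param_registry()
  expect_true(all(reg$mc_min <= reg$base & reg$base <= reg$mc_max))
  probs <- reg$role %in% c("probability", "utility")
  expect_true(all(reg$mc_min[probs] >= 0 & reg$mc_max[probs] <= 1))
  expect_true(all(reg$mc_min[reg$role == "cost"] >= 0))
})

test_that("load_defaults is idempotent and scope-resolved", {
  expect_identical(load_defaults("primary")$values, base_primary$values)
  expect_equal(base_primary$values[["p_first_pouchitis_no_ppx_annual"]], 0.4)
  expect_equal(base_secondary$values[["cost_vdz_dose"]], 6803)
  # scope-specific resolution of a shared clinical name
  expect_equal(param_registry("primary")[
    match("p_resp_cipro", param_registry("primary")$name), "mc_min"], 0.60)
  expect_equal(param_registry("secondary")[
    match("p_resp_cipro", param_registry("secondary")$name), "mc_min"], 0.50)
  # extended scope swaps the structural dual response for the 0.69 estimate
  ext <- load_defaults("primary_extended")
  expect_equal(ext$values[["p_resp_dual"]], 0.69)
  expect_true(all(c("cost_vdz_dose", "p_lor_vdz_annual") %in% names(ext$values)))
})

test_that("override has value semantics and enforces role bounds", {
  cheap <- override(base_primary, "cost_probiotic_2wk", 41)
  expect_equal(cheap$values[["cost_probiotic_2wk"]], 41)
  expect_equal(base_primary$values[["cost_probiotic_2wk"]], 87.2)  # untouched
  rest <- setdiff(names(base_primary$values), "cost_probiotic_2wk")
  expect_identical(cheap$values[rest], base_primary$values[rest])
  # identity override
  same <- override(base_primary, "utility_no_pouchitis", 0.91)
  expect_identical(same$values, base_primary$values)
  # values beyond the MC range but inside role bounds are allowed (sweeps)
  expect_silent(override(base_primary, "cost_first_episode_workup", 10000))
  expect_error(override(base_primary, "p_resp_cipro", 1.5), "bounds")
  expect_error(override(base_primary, "cost_cipro_2wk", -1), "bounds")
  expect_error(override(base_primary, "no_such_parameter", 1), "unknown")
})

test_that("triangular sampler matches the closed-form quantile function", {
  spec <- param_registry("primary")
  spec <- spec[spec$name == "p_recurrent_pouchitis_annual", ]
  expect_equal(sample_triangular(spec, 0), spec$mc_min)
  expect_equal(sample_triangular(spec, 1), spec$mc_max)
  # CDF at the mode of a triangular distribution is (mode-min)/(max-min)
  u_mode <- (spec$base - spec$mc_min) / (spec$mc_max - spec$mc_min)
  expect_equal(sample_triangular(spec, u_mode), spec$base, tolerance = 1e-12)
  u <- seq(0, 1, length.out = 101)
  q <- sample_triangular(spec, u)
  expect_true(all(diff(q) > 0))
  expect_error(sample_triangular(spec, 1.2), "\\[0, 1\\]")
  # empirical check against the analytic mean (min+mode+max)/3
  set.seed(11)
  draws <- sample_triangular(spec, runif(1e5))
  expect_true(all(draws >= spec$mc_min & draws <= spec$mc_max))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - (spec$mc_min + spec$base + spec$mc_max) / 3), 3 * se)
  # empirical CDF at the mode agrees with u_mode
  expect_lt(abs(mean(draws <= spec$base) - u_mode), 3 * sqrt(u_mode * (1 - u_mode) / 1e5))
})

test_that("validate_parameters reports violations as data", {
  expect_equal(nrow(validate_parameters(base_primary)), 0)
  bad <- base_primary
  bad$values[["p_resp_metro"]] <- -0.1   # bypass override() on purpose
  v <- validate_parameters(bad)
  expect_equal(v$parameter, "p_resp_metro")
  expect_match(v$rule, "probability")
  incomplete <- base_primary
  incomplete$values <- incomplete$values[
    names(incomplete$values) != "utility_active_pouchitis"]
  v2 <- validate_parameters(incomplete)
  expect_equal(v2$parameter, "utility_active_pouchitis")
  expect_equal(v2$rule, "missing")
})

test_that("registry exports to CSV with the documented columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  export_registry_csv(path, "secondary")
  got <- read.csv(path)
  expect_true(all(c("name", "role", "base", "mc_min", "mc_max", "time_basis",
                    "source") %in% names(got)))
  expect_equal(got$base[got$name == "cost_carp_eval"], 128.4)
})
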