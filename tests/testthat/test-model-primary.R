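# Primary prevention model structure: incidence, escalation ladder, variants.

test_that("two-year first-pouchitis incidence matches the closed form exactly", {
  tn <- run_cohort(arms_primary$no_prophylaxis, base_primary, 2)
  tp <- run_cohort(arms_primary$probiotic, base_primary, 2)
  expect_equal(tn$event_incidence$ever_pouchitis[[53]], 1 - 0.6^2,
               tolerance = 1e-10)
  expect_equal(tp$event_incidence$ever_pouchitis[[53]], 1 - 0.9^2,
               tolerance = 1e-10)
})

test_that("reach of dual antibiotics matches the reported cohort landmarks", {
  tn <- run_cohort(arms_primary$no_prophylaxis, base_primary, 2)
  tp <- run_cohort(arms_primary$probiotic, base_primary, 2)
  expect_lt(abs(tn$event_incidence$ever_dual[[53]] - 0.073), 0.015)
  expect_lt(abs(tp$event_incidence$ever_dual[[53]] - 0.020), 0.015)
})

test_that("perfect ciprofloxacin response shuts off all escalation", {
  ps <- override(base_primary, "p_resp_cipro", 1)
  arms <- build_primary(ps)
  tr <- run_cohort(arms$no_prophylaxis, ps, 2)
  expect_equal(tr$event_incidence$ever_metro[[53]], 0)
  expect_equal(tr$event_incidence$ever_dual[[53]], 0)
})

test_that("without first episodes the arms differ only by probiotic cost", {
  ps <- override(base_primary,
                 c("p_first_pouchitis_ppx_annual", "p_first_pouchitis_no_ppx_annual"),
                 0)
  arms <- build_primary(ps)
  tp <- run_cohort(arms$probiotic, ps, 2)
  tn <- run_cohort(arms$no_prophylaxis, ps, 2)
  expect_equal(tp$cumulative_qaly, tn$cumulative_qaly)
  expect_equal(tn$cumulative_cost, 0)
  expect_gt(tp$cumulative_cost, 0)
})

test_that("the empirical-workup variant shifts cost timing but not QALYs", {
  arms_emp <- build_primary(base_primary, "empirical_workup")
  for (arm in c("probiotic", "no_prophylaxis")) {
    tb <- run_cohort(arms_primary[[arm]], base_primary, 2)
    te <- run_cohort(arms_emp[[arm]], base_primary, 2)
    expect_equal(te$cumulative_qaly, tb$cumulative_qaly, tolerance = 1e-12)
    # deferring (and sometimes avoiding) the workup can only reduce cost
    expect_lt(te$cumulative_cost, tb$cumulative_cost)
    expect_identical(te$occupancy, tb$occupancy)
  }
})

test_that("the extended variant carries dual-antibiotic failures to biologics", {
  ps <- load_defaults("primary_extended")
  arms <- build_primary(ps, "extended_biologics")
  tr <- run_cohort(arms$no_prophylaxis, ps, 2)
  expect_gt(tr$event_incidence$ever_biologic[[53]], 0)
  expect_gt(tr$event_incidence$ever_ifx[[53]], 0)
  expect_lt(tr$event_incidence$ever_ifx[[53]],
            tr$event_incidence$ever_biologic[[53]])
  # and the headline conclusion is unchanged: still not cost-effective
  res <- cea_compare(run_cohort(arms$probiotic, ps, 2), tr)
  expect_equal(res$classification, "not_cost_effective")
  # shutting off VDZ failure modes empties the IFX pathway
  ps2 <- override(override(ps, "p_resp_vdz", 1), "p_lor_vdz_annual", 0)
  tr2 <- run_cohort(arms$no_prophylaxis, ps2, 2)
  expect_equal(tr2$event_incidence$ever_ifx[[53]], 0)
  # the base variant refuses a structural dual response below 1
  ps3 <- override(base_primary, "p_resp_dual", 0.9)
  expect_error(run_cohort(build_primary(base_primary)$probiotic, ps3, 2),
               "extended_biologics")
})

test_that("course costs map to the tabulated parameters and tunnel lengths", {
  expect_equal(antibiotic_course_cost("cipro", "primary"),
               list(parameter = "cost_cipro_2wk", tunnel_cycles = 1L))
  expect_equal(antibiotic_course_cost("dual", "primary"),
               list(parameter = "cost_dual_4wk", tunnel_cycles = 2L))
  expect_equal(antibiotic_course_cost("dual", "secondary"),
               list(parameter = "cost_dual_4wk", tunnel_cycles = 1L))
  expect_equal(base_primary$values[[antibiotic_course_cost("dual", "primary")$parameter]],
               270)
})

test_that("simulated trajectories never de-escalate the antibiotic ladder", {
  line <- c(well = 0, cipro_first = 1, rem_first = 1, cipro = 1, rem_cipro = 1,
            metro = 2, rem_metro = 2, dual_a = 3, dual_b = 3, rem_dual = 3)
  for (i in 1:40) {
    h <- simulate_patient(arms_primary$no_prophylaxis, base_primary, 2,
                          seed = 5000 + i)
    expect_true(all(diff(line[h$states]) >= 0), info = paste("patient", i))
  }
})
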