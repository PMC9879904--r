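test_that("treatment effect and branch QALYs follow the model conventions", {
  expect_equal(apply_treatment_effect(0.017, 0.10), 0.0153)
  expect_equal(apply_treatment_effect(0.3, 0), 0.3)
  expect_equal(apply_treatment_effect(0.3, 1), 0)
  expect_error(apply_treatment_effect(1.2, 0.1), "probability")
  expect_error(apply_treatment_effect(0.1, -0.1), "proportion")

  expect_equal(branch_qaly(0.77, 0), 0.77)
  expect_equal(branch_qaly(0.72, 0.0153), 0.714492) # 0.9847*0.72 + 0.0153*0.36
  expect_equal(branch_qaly(0.61, 1), 0.305) # everyone dies at midpoint
  expect_error(branch_qaly(1.2, 0), "utility")
})

test_that("strategy constructors wire the published base case correctly", {
  params <- base_case_parameters()

  ox <- make_oxmis_strategy(params)
  expect_equal(ox$assessment_cost, 57)
  expect_equal(ox$p_hrm, 0.25)
  expect_equal(ox$p_suicide_hrm_pre, 0.017)
  expect_equal(ox$p_suicide_lrm, 0.005)

  cl <- make_clinical_strategy(params)
  expect_equal(cl$assessment_cost, 253)
  expect_equal(cl$p_hrm, 0.5)
  expect_equal(cl$p_suicide_hrm_pre, 0.008)
  expect_equal(cl$p_suicide_lrm, 0.008)

  # degenerate strategy: flag nobody
  p0 <- parameter_set(p_high_oxmis = 0)
  expect_equal(make_oxmis_strategy(p0)$p_hrm, 0)

  # null treatment effect leaves both clinical branch risks identical
  pn <- parameter_set(hrm_risk_reduction = 0)
  cln <- make_clinical_strategy(pn)
  expect_equal(apply_treatment_effect(cln$p_suicide_hrm_pre,
                                      cln$hrm_risk_reduction),
               cln$p_suicide_lrm)
})

test_that("cohort expectations reproduce the published strategy means", {
  params <- base_case_parameters()
  ox <- evaluate_strategy(make_oxmis_strategy(params))
  cl <- evaluate_strategy(make_clinical_strategy(params))
  expect_equal(ox$expected_cost, 462.7195, tolerance = 1e-12)
  expect_equal(cl$expected_cost, 1062.476, tolerance = 1e-12)
  expect_equal(round(ox$expected_cost), 463)
  expect_equal(round(cl$expected_cost), 1062)
  expect_equal(ox$p_suicide, 0.007575, tolerance = 1e-12)
  expect_equal(cl$p_suicide, 0.0076, tolerance = 1e-12)
})

test_that("a free, risk-free strategy yields zero cost and full utility", {
  spec <- strategy_spec("null", assessment_cost = 0, p_hrm = 0.4,
                        p_suicide_hrm_pre = 0, p_suicide_lrm = 0,
                        hrm_risk_reduction = 0.1, cost_hrm = 0, cost_lrm = 0,
                        cost_suicide = 0, utility_base = 0.8,
                        utility_hrm_decrement = 0)
  out <- evaluate_strategy(spec)
  expect_equal(out$expected_cost, 0)
  expect_equal(out$expected_qaly, 0.8)
  expect_equal(out$p_suicide, 0)
})

test_that("tree evaluation agrees with explicit path enumeration", {
  set.seed(101)
  for (i in 1:100) {
    params <- random_parameter_set()
    for (mk in list(make_oxmis_strategy, make_clinical_strategy)) {
      spec <- mk(params)
      got <- evaluate_strategy(spec)
      want <- enumerate_paths_oracle(spec)
      expect_lt(abs(got$expected_cost - want$expected_cost), 1e-12)
      expect_lt(abs(got$expected_qaly - want$expected_qaly), 1e-12)
      expect_lt(abs(got$p_suicide - want$p_suicide), 1e-12)
    }
  }
})

test_that("path probabilities are a proper distribution over four paths", {
  set.seed(5)
  for (i in 1:20) {
    spec <- make_oxmis_strategy(random_parameter_set())
    paths <- strategy_paths(spec)
    expect_equal(nrow(paths), 4)
    expect_equal(sum(paths$probability), 1, tolerance = 1e-12)
    expect_true(all(paths$probability >= 0))
  }
})

test_that("expected cost and QALYs respond monotonically to drivers", {
  params <- base_case_parameters()
  base <- evaluate_strategy(make_oxmis_strategy(params))

  dearer <- parameter_set(cost_hrm = 2000)
  expect_gt(evaluate_strategy(make_oxmis_strategy(dearer))$expected_cost,
            base$expected_cost)

  stronger <- parameter_set(hrm_risk_reduction = 0.5)
  expect_gte(evaluate_strategy(make_oxmis_strategy(stronger))$expected_qaly,
             base$expected_qaly)

  # QALYs are capped at the base utility, attained only without deaths or
  # decrement exposure
  expect_lt(base$expected_qaly, params$utility_smi)
  pure <- strategy_spec("pure", 0, p_hrm = 0, p_suicide_hrm_pre = 0,
                        p_suicide_lrm = 0, hrm_risk_reduction = 0,
                        cost_hrm = 0, cost_lrm = 0, cost_suicide = 0,
                        utility_base = 0.77, utility_hrm_decrement = 0.05)
  expect_equal(evaluate_strategy(pure)$expected_qaly, 0.77)
})
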