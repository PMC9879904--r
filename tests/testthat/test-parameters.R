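test_that("the packaged base-case config matches the published inputs", {
  params <- load_parameters()
  expect_s3_class(params, "parameter_set")
  expect_identical(params, base_case_parameters())
  expect_equal(params$cost_hrm, 1615)
  expect_equal(params$cost_oxmis, 57)
  expect_equal(params$cost_clinical_assessment, 253)
  expect_equal(params$p_high_oxmis, 0.25)
  expect_equal(params$p_high_clinical, 0.5)
  expect_equal(params$p_suicide_high, 0.017)
  expect_equal(params$p_suicide_overall, 0.008)
  expect_equal(params$utility_smi, 0.77)
  expect_equal(params$utility_decrement_hrm, 0.05)
})

test_that("parameter validation rejects out-of-range and missing inputs", {
  base <- unclass(base_case_parameters())

  bad <- base
  bad$p_high_oxmis <- 1.2
  expect_error(validate_parameter_set(bad), "p_high_oxmis")

  bad <- base
  bad$cost_hrm <- -5
  expect_error(validate_parameter_set(bad), "cost_hrm")

  expect_error(validate_parameter_set(base[setdiff(names(base), "cost_lrm")]),
               "cost_lrm")

  bad <- base
  bad$p_suicide_high <- 0.004 # below the overall incidence
  expect_error(validate_parameter_set(bad), "p_suicide_high")

  bad <- base
  bad$utility_decrement_hrm <- 0.9 # would push the HRM utility negative
  expect_error(validate_parameter_set(bad), "utility")

  bad <- base
  bad$time_horizon_years <- 2
  expect_error(validate_parameter_set(bad), "one-year")
})

test_that("parameter sets round-trip through the YAML config exactly", {
  params <- base_case_parameters()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(params, path)
  reloaded <- load_parameters(path)
  for (f in names(params)) {
    expect_identical(as.numeric(reloaded[[f]]), as.numeric(params[[f]]),
                     info = f)
  }
})

test_that("the low-branch risk solves the overall-incidence mixture", {
  expect_equal(derive_p_suicide_low(0.25, 0.017, 0.008),
               (0.008 - 0.25 * 0.017) / 0.75)
  expect_equal(derive_p_suicide_low(0.25, 0.017, 0.008), 0.005)
  # limit: as nobody is flagged high, the low branch carries the incidence
  expect_equal(derive_p_suicide_low(0, 0.017, 0.008), 0.008)
  expect_error(derive_p_suicide_low(0.5, 0.02, 0.005), "negative")
  expect_error(derive_p_suicide_low(1, 0.017, 0.008), "p_high")

  set.seed(11)
  for (i in 1:50) {
    p <- random_parameter_set()
    p_low <- derive_p_suicide_low(p$p_high_oxmis, p$p_suicide_high,
                                  p$p_suicide_overall)
    expect_gte(p_low, 0)
    expect_lte(p_low, p$p_suicide_high)
    mixture <- p$p_high_oxmis * p$p_suicide_high +
      (1 - p$p_high_oxmis) * p_low
    expect_lt(abs(mixture - p$p_suicide_overall), 1e-12)
  }
})

test_that("the high-risk flag probability is the specificity complement", {
  expect_equal(p_flag_from_specificity(0.75), 0.25)
  expect_equal(p_flag_from_specificity(1), 0)
  expect_equal(p_flag_from_specificity(0), 1)
  expect_error(p_flag_from_specificity(1.5), "\\[0, 1\\]")
})
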