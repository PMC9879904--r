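test_that("moment matching recovers closed-form beta/gamma parameters", {
  g <- moment_match("gamma", 1615, 323)
  expect_equal(g$shape, 25)
  expect_equal(g$scale, 64.6)

  b <- moment_match("beta", 0.5, 0.25)
  expect_equal(b$shape1, 1.5)
  expect_equal(b$shape2, 1.5)

  f <- moment_match("fixed", 57)
  expect_equal(f$value, 57)

  expect_error(moment_match("beta", 0.5, 0.5), "infeasible")
  expect_error(moment_match("beta", 1.2, 0.1), "\\(0, 1\\)")
})

test_that("sampled distributions hit their target moments", {
  set.seed(99)
  x <- sample_dist(dist_spec("p_high_oxmis", "beta", 0.25, 0.05), 50000)
  expect_true(all(x > 0 & x < 1))
  expect_equal(mean(x), 0.25, tolerance = 0.01)
  expect_equal(sd(x), 0.05, tolerance = 0.05)

  y <- sample_dist(dist_spec("cost_hrm", "gamma", 1615, 323), 50000)
  expect_true(all(y > 0))
  expect_equal(mean(y), 1615, tolerance = 0.01)

  z <- sample_dist(dist_spec("cost_oxmis", "fixed", 57), 10)
  expect_identical(z, rep(57, 10))
})

test_that("the default PSA varies exactly the six published parameters", {
  specs <- default_psa_specs(base_case_parameters())
  expect_setequal(names(specs),
                  c("cost_oxmis", "cost_hrm", "cost_suicide",
                    "utility_decrement_hrm", "p_high_oxmis",
                    "p_suicide_high"))
  fams <- vapply(specs, `[[`, "", "family")
  expect_true(all(fams[c("cost_oxmis", "cost_hrm", "cost_suicide")] ==
                    "gamma"))
  expect_true(all(fams[c("utility_decrement_hrm", "p_high_oxmis",
                         "p_suicide_high")] == "beta"))
  # default dispersion: sd = 20% of the mean
  for (s in specs) expect_equal(s$sd, 0.2 * s$mean)
})

test_that("degenerate distributions reproduce the base case exactly", {
  params <- base_case_parameters()
  fixed <- lapply(default_psa_specs(params), function(s) {
    dist_spec(s$parameter, "fixed", s$mean)
  })
  res <- psa_run(params, specs = fixed, n = 50, seed = 3)
  base <- incremental(evaluate_strategy(make_oxmis_strategy(params)),
                      evaluate_strategy(make_clinical_strategy(params)))
  expect_true(all(res$draws$delta_cost == base$delta_cost))
  expect_true(all(res$draws$delta_qaly == base$delta_qaly))
  expect_equal(res$n_rejected, 0L)
})

test_that("PSA is seed-reproducible and conserves quadrant proportions", {
  params <- base_case_parameters()
  r1 <- psa_run(params, n = 300, seed = 12)
  r2 <- psa_run(params, n = 300, seed = 12)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$ceac, r2$ceac)

  expect_equal(r1$prop_dominant + r1$prop_sw + r1$prop_ne + r1$prop_inferior,
               1)
  expect_equal(r1$prop_cost_saving, r1$prop_dominant + r1$prop_sw)
  expect_true(all(r1$ceac$prob_cost_effective >= 0 &
                    r1$ceac$prob_cost_effective <= 1))
  # with every draw gaining QALYs, a higher threshold can only help
  if (all(r1$draws$delta_qaly > 0)) {
    expect_true(all(diff(r1$ceac$prob_cost_effective) >= 0))
  }
})

test_that("the PSA mean tracks the incremental result at the mean inputs", {
  params <- base_case_parameters()
  res <- psa_run(params, n = 2000, seed = 42)
  base <- incremental(evaluate_strategy(make_oxmis_strategy(params)),
                      evaluate_strategy(make_clinical_strategy(params)))
  se_cost <- sd(res$draws$delta_cost) / sqrt(res$n_draws)
  se_qaly <- sd(res$draws$delta_qaly) / sqrt(res$n_draws)
  expect_lt(abs(res$mean_delta_cost - base$delta_cost), 3 * se_cost)
  expect_lt(abs(res$mean_delta_qaly - base$delta_qaly), 3 * se_qaly)
})

test_that("one-way sensitivity analysis is exact at degenerate ranges and
          sorted by span", {
  params <- base_case_parameters()
  base_icer <- incremental(
    evaluate_strategy(make_oxmis_strategy(params)),
    evaluate_strategy(make_clinical_strategy(params)))$icer

  rows <- one_way_sa(params,
                     ranges = list(cost_hrm = c(1615, 1615),
                                   p_high_oxmis = c(0.25, 0.25)))
  expect_equal(rows$icer_at_low, rep(base_icer, 2))
  expect_equal(rows$icer_at_high, rep(base_icer, 2))
  expect_equal(rows$span, c(0, 0))

  tor <- one_way_sa(params)
  expect_equal(nrow(tor), 6)
  expect_true(all(diff(tor$span) <= 0)) # descending
  # every end re-evaluated here must match the path-enumeration oracle
  for (name in c("p_high_oxmis", "cost_hrm")) {
    rng <- default_one_way_ranges(params)[[name]]
    for (v in rng) {
      trial <- unclass(params)
      trial[[name]] <- v
      trial <- validate_parameter_set(trial)
      spec <- make_oxmis_strategy(trial)
      expect_lt(abs(evaluate_strategy(spec)$expected_cost -
                      enumerate_paths_oracle(spec)$expected_cost), 1e-12)
    }
  }
  expect_error(one_way_sa(params, ranges = list(p_high_oxmis = c(0.2, 1.3))),
               "p_high_oxmis")
})
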