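# Independent brute-force oracle: explicit enumeration of the four
# root-to-leaf paths, written as flat arithmetic with no code shared with
# the tree engine.
enumerate_paths_oracle <- function(spec) {
  a <- spec$assessment_cost
  p_die_hrm <- spec$p_suicide_hrm_pre * (1 - spec$hrm_risk_reduction)
  p_die_lrm <- spec$p_suicide_lrm
  u_hrm <- spec$utility_base - spec$utility_hrm_decrement
  u_lrm <- spec$utility_base

  paths <- list(
    list(prob = spec$p_hrm * p_die_hrm,
         cost = a + spec$cost_hrm + spec$cost_suicide,
         qaly = u_hrm / 2, died = TRUE),
    list(prob = spec$p_hrm * (1 - p_die_hrm),
         cost = a + spec$cost_hrm, qaly = u_hrm, died = FALSE),
    list(prob = (1 - spec$p_hrm) * p_die_lrm,
         cost = a + spec$cost_lrm + spec$cost_suicide,
         qaly = u_lrm / 2, died = TRUE),
    list(prob = (1 - spec$p_hrm) * (1 - p_die_lrm),
         cost = a + spec$cost_lrm, qaly = u_lrm, died = FALSE)
  )
  list(
    expected_cost = sum(vapply(paths, function(p) p$prob * p$cost, 0)),
    expected_qaly = sum(vapply(paths, function(p) p$prob * p$qaly, 0)),
    p_suicide = sum(vapply(paths, function(p) if (p$died) p$prob else 0, 0))
  )
}

# Random parameter set respecting every model invariant, including
# feasibility of the derived low-branch risk (p_high * p_suicide_high <=
# p_suicide_overall <= p_suicide_high).
random_parameter_set <- function() {
  overall <- stats::runif(1, 0.002, 0.05)
  p_high_risk <- stats::runif(1, overall, min(4 * overall, 0.15))
  ph_max <- min(0.9, 0.99 * overall / p_high_risk)
  u <- stats::runif(1, 0.4, 0.95)
  parameter_set(
    p_high_oxmis = stats::runif(1, 0.01, ph_max),
    p_high_clinical = stats::runif(1, 0.05, 0.95),
    p_suicide_high = p_high_risk,
    p_suicide_overall = overall,
    hrm_risk_reduction = stats::runif(1, 0, 0.5),
    cost_oxmis = stats::runif(1, 10, 200),
    cost_clinical_assessment = stats::runif(1, 50, 500),
    cost_hrm = stats::runif(1, 200, 5000),
    cost_lrm = stats::runif(1, 0, 100),
    cost_suicide = stats::runif(1, 0, 2000),
    utility_smi = u,
    utility_decrement_hrm = stats::runif(1, 0, min(0.3, u))
  )
}
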