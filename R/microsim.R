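#' Simulate individual patients through a strategy's decision tree
#'
#' Patient-level microsimulation of the one-year model: each patient is
#' flagged high-risk with probability `p_hrm`, then dies by suicide with the
#' branch's post-treatment annual risk. Costs accrue as
#' assessment + management + (suicide cost if the patient dies); QALYs equal
#' the branch utility, halved for decedents under the midpoint rule — the
#' same payoff conventions as the analytic tree, so cohort means are
#' unbiased estimates of [evaluate_strategy()]'s expectations. This is the
#' package's synthetic-data generator and brute-force oracle.
#'
#' @param spec A `strategy_spec`.
#' @param n Number of patients.
#' @param seed Integer seed; the same seed reproduces the same cohort.
#' @return A data frame of class `patient_cohort` with columns `patient_id`,
#'   `strategy`, `flagged_high`, `died_by_suicide`, `cost`, `qaly`.
#' @export
#' @examples
#' cohort <- simulate_cohort(make_oxmis_strategy(parameter_set()),
#'                           n = 1000, seed = 42)
#' mean(cohort$cost)
simulate_cohort <- function(spec, n, seed = 1) {
  spec <- validate_strategy_spec(spec)
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  set.seed(seed)

  flagged <- stats::rbinom(n, 1, spec$p_hrm) == 1
  p_die_hrm <- apply_treatment_effect(spec$p_suicide_hrm_pre,
                                      spec$hrm_risk_reduction)
  p_die <- ifelse(flagged, p_die_hrm, spec$p_suicide_lrm)
  died <- stats::rbinom(n, 1, p_die) == 1

  cost <- spec$assessment_cost +
    ifelse(flagged, spec$cost_hrm, spec$cost_lrm) +
    ifelse(died, spec$cost_suicide, 0)
  utility <- ifelse(flagged, spec$utility_base - spec$utility_hrm_decrement,
                    spec$utility_base)
  qaly <- utility * ifelse(died, 0.5, 1)

  structure(
    data.frame(patient_id = seq_len(n), strategy = spec$name,
               flagged_high = flagged, died_by_suicide = died,
               cost = cost, qaly = qaly, stringsAsFactors = FALSE),
    class = c("patient_cohort", "data.frame")
  )
}

#' Summarise a simulated cohort into a strategy outcome
#'
#' Computes cohort mean cost, mean QALYs and the suicide proportion, with
#' Monte Carlo standard errors, in the same shape as the analytic
#' [evaluate_strategy()] output so the two routes can be compared directly.
#'
#' @param records A `patient_cohort` from [simulate_cohort()]; all records
#'   must share one strategy label.
#' @return A `strategy_outcome` with additional fields `n`, `se_cost`,
#'   `se_qaly` and `se_p_suicide`.
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a nonempty patient cohort", call. = FALSE)
  }
  needed <- c("strategy", "flagged_high", "died_by_suicide", "cost", "qaly")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  labels <- unique(records$strategy)
  if (length(labels) != 1) {
    stop("records must share one strategy label; found: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  se <- function(x) stats::sd(x) / sqrt(n)
  p_suicide <- mean(records$died_by_suicide)
  structure(
    list(
      name = labels,
      expected_cost = mean(records$cost),
      expected_qaly = mean(records$qaly),
      p_suicide = p_suicide,
      n = n,
      se_cost = se(records$cost),
      se_qaly = se(records$qaly),
      se_p_suicide = sqrt(p_suicide * (1 - p_suicide) / n)
    ),
    class = "strategy_outcome"
  )
}
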