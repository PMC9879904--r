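#' Convert a probability to odds
#'
#' @param p Probability, in `[0, 1)`.
#' @return `p / (1 - p)`.
#' @export
#' @examples
#' prob_to_odds(0.5) # 1
prob_to_odds <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p must be a probability in [0, 1]", call. = FALSE)
  }
  if (any(p == 1)) {
    stop("p = 1 gives infinite odds", call. = FALSE)
  }
  p / (1 - p)
}

#' Convert odds to a probability
#'
#' @param odds Non-negative odds.
#' @return `odds / (1 + odds)`.
#' @export
odds_to_prob <- function(odds) {
  if (any(!is.finite(odds)) || any(odds < 0)) {
    stop("odds must be finite and >= 0", call. = FALSE)
  }
  odds / (1 + odds)
}

#' Test characteristics of a risk assessment
#'
#' @param sensitivity True positive rate, in `[0, 1]`.
#' @param specificity True negative rate, in `[0, 1]`.
#' @return An object of class `test_characteristics`.
#' @export
test_characteristics <- function(sensitivity, specificity) {
  for (v in list(sensitivity = sensitivity, specificity = specificity)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      stop("sensitivity and specificity must be single numbers in [0, 1]",
           call. = FALSE)
    }
  }
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "test_characteristics")
}

#' Positive likelihood ratio of a test
#'
#' LR+ = sensitivity / (1 - specificity): the factor by which a positive
#' test result multiplies the pre-test odds.
#'
#' @param tc A [test_characteristics()] object, or a sensitivity value when
#'   `specificity` is also given.
#' @param specificity Optional; supply together with a bare sensitivity in
#'   `tc`.
#' @return The positive likelihood ratio.
#' @export
#' @examples
#' positive_likelihood_ratio(test_characteristics(0.5, 0.75)) # 2
positive_likelihood_ratio <- function(tc, specificity = NULL) {
  if (!inherits(tc, "test_characteristics")) {
    tc <- test_characteristics(tc, specificity)
  }
  if (tc$specificity >= 1) {
    stop("LR+ is undefined when specificity = 1 (no false positives)",
         call. = FALSE)
  }
  tc$sensitivity / (1 - tc$specificity)
}

#' Post-test probability via likelihood-ratio updating
#'
#' Converts the pre-test probability to odds, multiplies by the likelihood
#' ratio, and converts back. Monotone increasing in `lr`.
#'
#' @param pretest Pre-test probability, in `[0, 1)`.
#' @param lr Likelihood ratio, `>= 0`.
#' @return The post-test probability.
#' @export
#' @examples
#' posttest_probability(0.5, 0.69 / 0.31) # 0.69
posttest_probability <- function(pretest, lr) {
  if (any(!is.finite(lr)) || any(lr < 0)) {
    stop("lr must be finite and >= 0", call. = FALSE)
  }
  odds_to_prob(prob_to_odds(pretest) * lr)
}

#' Sequential (clinical-then-OxMIS) assessment strategy
#'
#' Scenario arm in which every patient receives the clinical psychosocial
#' assessment followed by OxMIS, paying both assessment costs. OxMIS updates
#' the probability that a clinical high-risk call is a true positive from its
#' pre-test value (0.5) to a post-test probability via likelihood-ratio
#' updating; the HRM entry probability is then reconstructed as
#' `1 - posttest`. This mapping is a reconstruction: it is the simple
#' mapping under which the scenario arm reproduces the published per-person
#' saving of the sequential analysis. Branch suicide risks are those of the
#' OxMIS strategy (high stratum 0.017 pre-treatment; low branch derived from
#' the mixture constraint).
#'
#' @param params A validated [parameter_set()].
#' @param posttest Post-test probability of a correct high-risk call
#'   (default 0.69, the published update from 0.5). Ignored when
#'   `sensitivity` and `specificity` are supplied.
#' @param sensitivity,specificity Optional test characteristics from which
#'   the post-test probability is computed via LR+ applied to `pretest`.
#' @param pretest Pre-test probability (default 0.5, the clinical arm's
#'   high-risk assignment probability).
#' @return A `strategy_spec` for the sequential arm.
#' @export
#' @examples
#' seq_arm <- make_sequential_strategy(parameter_set())
#' seq_arm$p_hrm # 0.31
make_sequential_strategy <- function(params, posttest = 0.69,
                                     sensitivity = NULL, specificity = NULL,
                                     pretest = 0.5) {
  params <- validate_parameter_set(params)
  if (!is.null(sensitivity) || !is.null(specificity)) {
    if (is.null(sensitivity) || is.null(specificity)) {
      stop("supply both sensitivity and specificity, or neither",
           call. = FALSE)
    }
    lr <- positive_likelihood_ratio(test_characteristics(sensitivity,
                                                         specificity))
    posttest <- posttest_probability(pretest, lr)
  }
  if (!is.numeric(posttest) || length(posttest) != 1 ||
      !is.finite(posttest) || posttest < 0 || posttest > 1) {
    stop("posttest must be a single probability in [0, 1]", call. = FALSE)
  }
  strategy_spec(
    name = "sequential",
    assessment_cost = params$cost_clinical_assessment + params$cost_oxmis,
    p_hrm = 1 - posttest,
    p_suicide_hrm_pre = params$p_suicide_high,
    p_suicide_lrm = derive_p_suicide_low(params$p_high_oxmis,
                                         params$p_suicide_high,
                                         params$p_suicide_overall),
    hrm_risk_reduction = params$hrm_risk_reduction,
    cost_hrm = params$cost_hrm,
    cost_lrm = params$cost_lrm,
    cost_suicide = params$cost_suicide,
    utility_base = params$utility_smi,
    utility_hrm_decrement = params$utility_decrement_hrm
  )
}
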