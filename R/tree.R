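#' Apply the high-risk-management treatment effect
#'
#' Multiplies a pre-treatment annual suicide risk by `1 - reduction`, the
#' relative risk reduction attributed to high-risk management.
#'
#' @param p_pre Pre-treatment annual suicide probability, in `[0, 1]`.
#' @param reduction Relative risk reduction, in `[0, 1]`.
#' @return Post-treatment suicide probability.
#' @export
#' @examples
#' apply_treatment_effect(0.017, 0.10) # 0.0153
apply_treatment_effect <- function(p_pre, reduction) {
  if (any(!is.finite(p_pre)) || any(p_pre < 0) || any(p_pre > 1)) {
    stop("p_pre must be a probability in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(reduction)) || any(reduction < 0) || any(reduction > 1)) {
    stop("reduction must be a proportion in [0, 1]", call. = FALSE)
  }
  p_pre * (1 - reduction)
}

#' Expected QALYs in one branch over the one-year horizon
#'
#' Survivors accrue the branch utility for the full year; decedents accrue
#' half of it, under the convention that suicide occurs at the midpoint of
#' the year (six months after assessment).
#'
#' @param utility Branch utility, in `[0, 1]`.
#' @param p_die Annual probability of death by suicide in the branch.
#' @return Expected QALYs: `(1 - p_die) * utility + p_die * utility / 2`.
#' @export
#' @examples
#' branch_qaly(0.77, 0)       # 0.77
#' branch_qaly(0.72, 0.0153)  # 0.714492
branch_qaly <- function(utility, p_die) {
  if (any(!is.finite(utility)) || any(utility < 0) || any(utility > 1)) {
    stop("utility must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(p_die)) || any(p_die < 0) || any(p_die > 1)) {
    stop("p_die must be a probability in [0, 1]", call. = FALSE)
  }
  (1 - p_die) * utility + p_die * utility / 2
}

#' Construct one arm of the comparison
#'
#' A `strategy_spec` describes one assessment strategy: the cost charged to
#' every patient at the root, the probability of high-risk management (HRM)
#' assignment, branch-level annual suicide risks, the HRM treatment effect,
#' management and suicide-event costs, and the survivors' utilities.
#'
#' @param name Strategy label.
#' @param assessment_cost GBP charged to every patient at the root.
#' @param p_hrm Probability of HRM assignment.
#' @param p_suicide_hrm_pre Annual suicide risk in the HRM branch before the
#'   treatment effect.
#' @param p_suicide_lrm Annual suicide risk in the LRM branch (no treatment
#'   effect is applied there).
#' @param hrm_risk_reduction Relative risk reduction applied in the HRM
#'   branch.
#' @param cost_hrm,cost_lrm,cost_suicide Management and suicide-event costs,
#'   GBP.
#' @param utility_base Annual utility of survivors not on HRM.
#' @param utility_hrm_decrement Utility decrement applied in the HRM branch.
#' @return An object of class `strategy_spec`.
#' @seealso [make_oxmis_strategy()], [make_clinical_strategy()],
#'   [evaluate_strategy()]
#' @export
strategy_spec <- function(name, assessment_cost, p_hrm, p_suicide_hrm_pre,
                          p_suicide_lrm, hrm_risk_reduction, cost_hrm,
                          cost_lrm, cost_suicide, utility_base,
                          utility_hrm_decrement) {
  spec <- list(
    name = as.character(name),
    assessment_cost = assessment_cost,
    p_hrm = p_hrm,
    p_suicide_hrm_pre = p_suicide_hrm_pre,
    p_suicide_lrm = p_suicide_lrm,
    hrm_risk_reduction = hrm_risk_reduction,
    cost_hrm = cost_hrm,
    cost_lrm = cost_lrm,
    cost_suicide = cost_suicide,
    utility_base = utility_base,
    utility_hrm_decrement = utility_hrm_decrement
  )
  validate_strategy_spec(spec)
}

#' @rdname strategy_spec
#' @param spec A candidate strategy specification (named list).
#' @export
validate_strategy_spec <- function(spec) {
  needed <- c("name", "assessment_cost", "p_hrm", "p_suicide_hrm_pre",
              "p_suicide_lrm", "hrm_risk_reduction", "cost_hrm", "cost_lrm",
              "cost_suicide", "utility_base", "utility_hrm_decrement")
  missing <- setdiff(needed, names(spec))
  if (length(missing) > 0) {
    stop("strategy spec is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- setdiff(needed, "name")
  for (f in num) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("strategy field '", f, "' must be a single finite number",
           call. = FALSE)
    }
  }
  for (f in c("p_hrm", "p_suicide_hrm_pre", "p_suicide_lrm",
              "hrm_risk_reduction")) {
    if (spec[[f]] < 0 || spec[[f]] > 1) {
      stop("strategy field '", f, "' must lie in [0, 1]; got ", spec[[f]],
           call. = FALSE)
    }
  }
  for (f in c("assessment_cost", "cost_hrm", "cost_lrm", "cost_suicide")) {
    if (spec[[f]] < 0) {
      stop("strategy field '", f, "' must be >= 0; got ", spec[[f]],
           call. = FALSE)
    }
  }
  p_post <- apply_treatment_effect(spec$p_suicide_hrm_pre,
                                   spec$hrm_risk_reduction)
  if (p_post < 0 || p_post > 1) {
    stop("post-treatment HRM suicide risk must lie in [0, 1]", call. = FALSE)
  }
  u_hrm <- spec$utility_base - spec$utility_hrm_decrement
  if (spec$utility_base < 0 || spec$utility_base > 1 || u_hrm < 0) {
    stop("utilities must lie in [0, 1] and the HRM-branch utility ",
         "(utility_base - utility_hrm_decrement) must be >= 0",
         call. = FALSE)
  }
  structure(spec, class = "strategy_spec")
}

#' OxMIS assessment strategy from a parameter set
#'
#' Every patient pays the OxMIS assessment cost; a proportion
#' `p_high_oxmis` (one minus the tool's specificity) enters HRM at the
#' high-stratum suicide risk, and the remainder enter LRM at the low-branch
#' risk derived from the overall-incidence mixture constraint
#' (see [derive_p_suicide_low()]).
#'
#' @param params A validated [parameter_set()].
#' @return A `strategy_spec` for the OxMIS arm.
#' @export
make_oxmis_strategy <- function(params) {
  params <- validate_parameter_set(params)
  strategy_spec(
    name = "oxmis",
    assessment_cost = params$cost_oxmis,
    p_hrm = params$p_high_oxmis,
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

#' Clinical-judgment strategy from a parameter set
#'
#' Every patient pays the psychosocial assessment cost; half (base case)
#' are judged high-risk. Clinical flagging is treated as uninformative for
#' risk, so both branches start at the population 12-month incidence; the
#' HRM branch then receives the relative risk reduction.
#'
#' @param params A validated [parameter_set()].
#' @return A `strategy_spec` for the clinical-judgment arm.
#' @export
make_clinical_strategy <- function(params) {
  params <- validate_parameter_set(params)
  strategy_spec(
    name = "clinical",
    assessment_cost = params$cost_clinical_assessment,
    p_hrm = params$p_high_clinical,
    p_suicide_hrm_pre = params$p_suicide_overall,
    p_suicide_lrm = params$p_suicide_overall,
    hrm_risk_reduction = params$hrm_risk_reduction,
    cost_hrm = params$cost_hrm,
    cost_lrm = params$cost_lrm,
    cost_suicide = params$cost_suicide,
    utility_base = params$utility_smi,
    utility_hrm_decrement = params$utility_decrement_hrm
  )
}

#' Explicit decision-tree representation of a strategy
#'
#' Builds the strategy's tree as nested chance nodes rather than hard-coded
#' arithmetic, so path enumeration and the microsimulation share one
#' definition of the model structure. The root chance node splits
#' HRM/LRM; each management branch splits die/survive. Costs accrue on
#' branches; utilities are resolved at the leaves with the midpoint rule
#' for decedents.
#'
#' @param spec A `strategy_spec`.
#' @return A nested list of nodes. Chance nodes have `type = "chance"` and a
#'   list of branches (each with `label`, `prob`, `cost`, `node`); leaves
#'   have `type = "leaf"`, a `qaly` payoff and a `died` indicator.
#' @export
strategy_tree <- function(spec) {
  spec <- validate_strategy_spec(spec)
  u_hrm <- spec$utility_base - spec$utility_hrm_decrement
  p_die_hrm <- apply_treatment_effect(spec$p_suicide_hrm_pre,
                                      spec$hrm_risk_reduction)

  outcome_node <- function(p_die, utility) {
    list(
      type = "chance",
      branches = list(
        list(label = "suicide", prob = p_die, cost = spec$cost_suicide,
             node = list(type = "leaf", qaly = utility / 2, died = TRUE)),
        list(label = "survive", prob = 1 - p_die, cost = 0,
             node = list(type = "leaf", qaly = utility, died = FALSE))
      )
    )
  }

  list(
    type = "chance",
    root_cost = spec$assessment_cost,
    branches = list(
      list(label = "hrm", prob = spec$p_hrm, cost = spec$cost_hrm,
           node = outcome_node(p_die_hrm, u_hrm)),
      list(label = "lrm", prob = 1 - spec$p_hrm, cost = spec$cost_lrm,
           node = outcome_node(spec$p_suicide_lrm, spec$utility_base))
    )
  )
}

#' Enumerate all root-to-leaf paths of a strategy tree
#'
#' @param spec A `strategy_spec`.
#' @return A data frame with one row per path: `path` (label), `probability`,
#'   `cost` (total accrued along the path, including the root assessment
#'   cost), `qaly` (leaf payoff) and `died` (logical).
#' @export
strategy_paths <- function(spec) {
  tree <- strategy_tree(spec)
  acc <- list(path = character(0), probability = numeric(0),
              cost = numeric(0), qaly = numeric(0), died = logical(0))
  walk <- function(node, prob, cost, labels) {
    if (node$type == "leaf") {
      acc$path <<- c(acc$path, paste(labels, collapse = ":"))
      acc$probability <<- c(acc$probability, prob)
      acc$cost <<- c(acc$cost, cost)
      acc$qaly <<- c(acc$qaly, node$qaly)
      acc$died <<- c(acc$died, node$died)
      return(invisible(NULL))
    }
    for (b in node$branches) {
      walk(b$node, prob * b$prob, cost + b$cost, c(labels, b$label))
    }
  }
  walk(tree, prob = 1, cost = tree$root_cost, labels = character(0))
  data.frame(acc, stringsAsFactors = FALSE)
}

#' Evaluate the cohort expectations of a strategy
#'
#' Computes the expected per-patient cost, expected QALYs and the
#' cohort-level annual suicide probability over the one-year horizon by
#' probability-weighting the strategy's root-to-leaf paths.
#'
#' @param spec A `strategy_spec`.
#' @return An object of class `strategy_outcome` with fields `name`,
#'   `expected_cost` (GBP per patient), `expected_qaly` and `p_suicide`.
#' @export
#' @examples
#' params <- parameter_set()
#' evaluate_strategy(make_oxmis_strategy(params))$expected_cost # 462.7195
evaluate_strategy <- function(spec) {
  spec <- validate_strategy_spec(spec)
  paths <- strategy_paths(spec)
  out <- structure(
    list(
      name = spec$name,
      expected_cost = sum(paths$probability * paths$cost),
      expected_qaly = sum(paths$probability * paths$qaly),
      p_suicide = sum(paths$probability[paths$died])
    ),
    class = "strategy_outcome"
  )
  if (out$expected_cost < spec$assessment_cost - 1e-9) {
    stop("internal error: expected cost below the assessment cost",
         call. = FALSE)
  }
  if (out$expected_qaly < 0 || out$expected_qaly > spec$utility_base + 1e-12) {
    stop("internal error: expected QALYs outside [0, utility_base]",
         call. = FALSE)
  }
  out
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("Strategy '%s': expected cost £%.2f, expected QALYs %.5f, annual suicide probability %.5f\n",
              x$name, x$expected_cost, x$expected_qaly, x$p_suicide))
  invisible(x)
}

#' @export
as.data.frame.strategy_outcome <- function(x, ...) {
  data.frame(name = x$name, expected_cost = x$expected_cost,
             expected_qaly = x$expected_qaly, p_suicide = x$p_suicide,
             stringsAsFactors = FALSE)
}
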