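#' Model parameter set
#'
#' Constructs and validates the full set of inputs to the one-year
#' decision-tree model: risk-stratification probabilities, annual suicide
#' risks, unit costs (GBP) and utilities. The defaults are the published
#' base case.
#'
#' @param p_high_oxmis Probability of being assigned high-risk management
#'   (HRM) under OxMIS assessment; equals one minus the tool's specificity
#'   (base 0.25).
#' @param p_high_clinical Probability of HRM assignment under unstructured
#'   clinical judgment (base 0.5).
#' @param p_suicide_high Annual suicide risk in the OxMIS high-risk stratum
#'   before any treatment effect (base 0.017).
#' @param p_suicide_overall Twelve-month suicide incidence in the severe
#'   mental illness (SMI) population (base 0.008).
#' @param hrm_risk_reduction Relative reduction in suicide risk conferred by
#'   HRM (base 0.10).
#' @param cost_oxmis Cost of administering the OxMIS assessment, GBP
#'   (base 57).
#' @param cost_clinical_assessment Cost of an unstructured psychosocial risk
#'   assessment, GBP (base 253).
#' @param cost_hrm Cost of the high-risk management package, GBP (base 1615).
#' @param cost_lrm Cost of low-risk management, GBP (base 0).
#' @param cost_suicide Direct emergency and health-service cost of a suicide,
#'   GBP (base 260).
#' @param utility_smi Annual utility of living with SMI, in `[0, 1]`
#'   (base 0.77).
#' @param utility_decrement_hrm Disutility of HRM treatment (base 0.05).
#' @param utility_death Utility of the state of death by suicide (base 0).
#' @param time_horizon_years Time horizon; the model is defined only for one
#'   year.
#' @param wtp_threshold Willingness-to-pay threshold, GBP per QALY, used for
#'   net monetary benefit and acceptability curves (default 20000).
#'
#' @return An object of class `parameter_set`: a named list of the validated
#'   inputs.
#' @seealso [load_parameters()], [derive_p_suicide_low()]
#' @export
#' @examples
#' params <- parameter_set()
#' params$cost_hrm
parameter_set <- function(p_high_oxmis = 0.25,
                          p_high_clinical = 0.5,
                          p_suicide_high = 0.017,
                          p_suicide_overall = 0.008,
                          hrm_risk_reduction = 0.10,
                          cost_oxmis = 57,
                          cost_clinical_assessment = 253,
                          cost_hrm = 1615,
                          cost_lrm = 0,
                          cost_suicide = 260,
                          utility_smi = 0.77,
                          utility_decrement_hrm = 0.05,
                          utility_death = 0,
                          time_horizon_years = 1,
                          wtp_threshold = 20000) {
  params <- list(
    p_high_oxmis = p_high_oxmis,
    p_high_clinical = p_high_clinical,
    p_suicide_high = p_suicide_high,
    p_suicide_overall = p_suicide_overall,
    hrm_risk_reduction = hrm_risk_reduction,
    cost_oxmis = cost_oxmis,
    cost_clinical_assessment = cost_clinical_assessment,
    cost_hrm = cost_hrm,
    cost_lrm = cost_lrm,
    cost_suicide = cost_suicide,
    utility_smi = utility_smi,
    utility_decrement_hrm = utility_decrement_hrm,
    utility_death = utility_death,
    time_horizon_years = time_horizon_years,
    wtp_threshold = wtp_threshold
  )
  validate_parameter_set(params)
}

#' @rdname parameter_set
#' @details `base_case_parameters()` returns the packaged base case, i.e.
#'   `parameter_set()` with all defaults.
#' @export
base_case_parameters <- function() {
  parameter_set()
}

.parameter_fields <- c(
  "p_high_oxmis", "p_high_clinical", "p_suicide_high", "p_suicide_overall",
  "hrm_risk_reduction", "cost_oxmis", "cost_clinical_assessment",
  "cost_hrm", "cost_lrm", "cost_suicide", "utility_smi",
  "utility_decrement_hrm", "utility_death", "time_horizon_years",
  "wtp_threshold"
)

.probability_fields <- c(
  "p_high_oxmis", "p_high_clinical", "p_suicide_high", "p_suicide_overall",
  "hrm_risk_reduction"
)

.cost_fields <- c(
  "cost_oxmis", "cost_clinical_assessment", "cost_hrm", "cost_lrm",
  "cost_suicide"
)

#' Validate a parameter set
#'
#' Checks every model invariant: probabilities in `[0, 1]`, non-negative
#' costs, utilities in `[0, 1]`, a non-negative HRM-branch utility, the
#' high-risk stratum enrichment `p_suicide_high >= p_suicide_overall`, and
#' the fixed one-year horizon.
#'
#' @param params A named list with the fields of [parameter_set()].
#' @return The input, classed as `parameter_set`, invisibly unchanged.
#' @export
validate_parameter_set <- function(params) {
  if (!is.list(params)) {
    stop("parameters must be supplied as a named list", call. = FALSE)
  }
  missing <- setdiff(.parameter_fields, names(params))
  if (length(missing) > 0) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  params <- params[.parameter_fields]
  for (f in .parameter_fields) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", f, "' must be a single finite number",
           call. = FALSE)
    }
    params[[f]] <- as.numeric(v) # configs may parse whole numbers as integer
  }
  for (f in .probability_fields) {
    v <- params[[f]]
    if (v < 0 || v > 1) {
      stop("parameter '", f, "' is a probability and must lie in [0, 1]; ",
           "got ", v, call. = FALSE)
    }
  }
  for (f in .cost_fields) {
    if (params[[f]] < 0) {
      stop("parameter '", f, "' is a cost and must be >= 0; got ",
           params[[f]], call. = FALSE)
    }
  }
  for (f in c("utility_smi", "utility_decrement_hrm", "utility_death")) {
    v <- params[[f]]
    if (v < 0 || v > 1) {
      stop("parameter '", f, "' is a utility quantity and must lie in ",
           "[0, 1]; got ", v, call. = FALSE)
    }
  }
  if (params$utility_smi - params$utility_decrement_hrm < 0) {
    stop("utility_smi - utility_decrement_hrm must be >= 0 ",
         "(HRM-branch utility cannot be negative)", call. = FALSE)
  }
  if (params$p_suicide_high < params$p_suicide_overall) {
    stop("p_suicide_high must be >= p_suicide_overall ",
         "(the high-risk stratum is enriched for suicide)", call. = FALSE)
  }
  if (params$time_horizon_years != 1) {
    stop("time_horizon_years must equal 1: the model is defined only ",
         "for a one-year horizon", call. = FALSE)
  }
  structure(params, class = "parameter_set")
}

#' Load model parameters from a config file or list
#'
#' Reads a flat key-value YAML config (field names as in [parameter_set()])
#' and validates it. Passing `NULL` or `"base_case"` loads the packaged
#' base-case config shipped at `inst/extdata/base_case.yaml`.
#'
#' @param config `NULL` or `"base_case"` for the packaged base case, a path
#'   to a YAML file, or a named list of parameter values.
#' @return A validated `parameter_set`.
#' @export
#' @examples
#' load_parameters()$cost_oxmis
load_parameters <- function(config = NULL) {
  if (is.null(config) || identical(config, "base_case")) {
    config <- system.file("extdata", "base_case.yaml", package = "oxmiscea",
                          mustWork = TRUE)
  }
  if (inherits(config, "parameter_set")) {
    return(validate_parameter_set(unclass(config)))
  }
  if (is.character(config)) {
    if (length(config) != 1 || !file.exists(config)) {
      stop("config file not found: ", paste(config, collapse = ", "),
           call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  validate_parameter_set(config)
}

#' Write a parameter set to a YAML config file
#'
#' The written file round-trips: reloading it with [load_parameters()]
#' reproduces every numeric field exactly.
#'
#' @param params A `parameter_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  params <- validate_parameter_set(params)
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Decision-model parameter set (1-year horizon)\n")
  df <- data.frame(parameter = names(x),
                   value = unlist(x, use.names = FALSE))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Solve for the low-risk-branch suicide risk
#'
#' The model states the annual suicide risk in the high-risk stratum and the
#' overall 12-month incidence, but not the low-risk branch risk. This closes
#' the model by solving the mixture constraint
#' `p_high * p_suicide_high + (1 - p_high) * p_low = p_suicide_overall`
#' for `p_low`, so the cohort reproduces the overall incidence.
#'
#' @param p_high Probability of high-risk assignment, strictly in `(0, 1)`.
#' @param p_suicide_high Annual suicide risk in the high-risk stratum.
#' @param p_suicide_overall Overall 12-month suicide incidence.
#' @return The low-branch annual suicide risk, in `[0, p_suicide_high]`.
#' @export
#' @examples
#' derive_p_suicide_low(0.25, 0.017, 0.008) # 0.005
derive_p_suicide_low <- function(p_high, p_suicide_high, p_suicide_overall) {
  stopifnot(is.numeric(p_high), is.numeric(p_suicide_high),
            is.numeric(p_suicide_overall))
  if (p_high < 0 || p_high >= 1) {
    stop("p_high must lie in [0, 1) for the mixture to be solvable",
         call. = FALSE)
  }
  p_low <- (p_suicide_overall - p_high * p_suicide_high) / (1 - p_high)
  if (p_low < 0) {
    stop("mixture constraint cannot be satisfied: ",
         "p_high * p_suicide_high exceeds p_suicide_overall, ",
         "implying a negative low-branch risk (", signif(p_low, 6), ")",
         call. = FALSE)
  }
  if (p_low > p_suicide_high) {
    stop("mixture constraint cannot be satisfied: the solved low-branch ",
         "risk (", signif(p_low, 6), ") exceeds the high-branch risk (",
         p_suicide_high, ")", call. = FALSE)
  }
  p_low
}

#' High-risk flag probability from test specificity
#'
#' The proportion assigned to high-risk management under a risk tool equals
#' the proportion flagged positive among a predominantly non-case
#' population, i.e. one minus the tool's specificity (true negative rate).
#'
#' @param specificity True negative rate, in `[0, 1]`.
#' @return `1 - specificity`.
#' @export
#' @examples
#' p_flag_from_specificity(0.75) # 0.25
p_flag_from_specificity <- function(specificity) {
  if (!is.numeric(specificity) || length(specificity) != 1 ||
      !is.finite(specificity) || specificity < 0 || specificity > 1) {
    stop("specificity must be a single number in [0, 1]", call. = FALSE)
  }
  1 - specificity
}
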