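round_gbp <- function(x) round(x)

write_outputs <- function(out_dir, files) {
  if (is.null(out_dir)) return(character(0))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (name in names(files)) {
    path <- file.path(out_dir, name)
    obj <- files[[name]]
    if (grepl("\\.json$", name)) {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    } else {
      utils::write.csv(obj, path, row.names = FALSE)
    }
    written <- c(written, path)
  }
  written
}

write_manifest <- function(out_dir, command, config, seed, outputs) {
  if (is.null(out_dir)) return(invisible(NULL))
  manifest <- list(
    command = command,
    config = if (is.character(config)) config else "inline",
    seed = seed,
    package_version = as.character(utils::packageVersion("oxmiscea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Base-case cohort analysis
#'
#' Evaluates the OxMIS and clinical-judgment strategies on a parameter set
#' and reports both strategy outcomes, the incremental result, and rounded
#' headline values (costs to the nearest pound, QALY gain to two decimals).
#'
#' @param config Anything accepted by [load_parameters()] (default: the
#'   packaged base case).
#' @param out_dir Optional output directory; when given, `strategies.csv`,
#'   `incremental.csv` and a `manifest.json` are written there.
#' @param wtp Willingness-to-pay threshold; defaults to the config's
#'   `wtp_threshold`.
#' @return A list with `outcomes` (data frame, one row per strategy),
#'   `incremental` (an `incremental_result`) and `headline` (rounded
#'   values: per-arm costs, saving, QALY gain).
#' @export
#' @examples
#' run_base_case()$headline
run_base_case <- function(config = NULL, out_dir = NULL, wtp = NULL) {
  params <- load_parameters(config)
  wtp <- if (is.null(wtp)) params$wtp_threshold else wtp
  o_ox <- evaluate_strategy(make_oxmis_strategy(params))
  o_cl <- evaluate_strategy(make_clinical_strategy(params))
  inc <- incremental(o_ox, o_cl, wtp = wtp)
  outcomes <- rbind(as.data.frame(o_ox), as.data.frame(o_cl))
  headline <- list(
    cost_oxmis_arm = round_gbp(o_ox$expected_cost),
    cost_clinical_arm = round_gbp(o_cl$expected_cost),
    saving_per_patient = round_gbp(o_cl$expected_cost) -
      round_gbp(o_ox$expected_cost),
    qaly_gain = round(inc$delta_qaly, 2),
    dominance = inc$dominance
  )
  written <- write_outputs(out_dir, list(
    "strategies.csv" = outcomes,
    "incremental.csv" = as.data.frame(inc),
    "headline.json" = headline
  ))
  write_manifest(out_dir, "base-case", config, NA_integer_, written)
  list(outcomes = outcomes, incremental = inc, headline = headline)
}

#' Sequential-scenario analysis
#'
#' Evaluates the sequential (clinical-then-OxMIS) strategy against clinical
#' judgment alone, with the HRM entry probability reconstructed from the
#' post-test probability (see [make_sequential_strategy()]).
#'
#' @inheritParams run_base_case
#' @param posttest Post-test probability of a correct high-risk clinical
#'   call after OxMIS (default 0.69).
#' @param sensitivity,specificity Optional test characteristics from which
#'   the post-test probability is derived instead.
#' @return As [run_base_case()], for the sequential comparison.
#' @export
run_scenario <- function(config = NULL, posttest = 0.69, sensitivity = NULL,
                         specificity = NULL, out_dir = NULL, wtp = NULL) {
  params <- load_parameters(config)
  wtp <- if (is.null(wtp)) params$wtp_threshold else wtp
  o_seq <- evaluate_strategy(make_sequential_strategy(
    params, posttest = posttest, sensitivity = sensitivity,
    specificity = specificity))
  o_cl <- evaluate_strategy(make_clinical_strategy(params))
  inc <- incremental(o_seq, o_cl, wtp = wtp)
  outcomes <- rbind(as.data.frame(o_seq), as.data.frame(o_cl))
  headline <- list(
    cost_sequential_arm = round_gbp(o_seq$expected_cost),
    cost_clinical_arm = round_gbp(o_cl$expected_cost),
    incremental_cost = round_gbp(inc$delta_cost),
    saving_per_patient = abs(round_gbp(inc$delta_cost)),
    qaly_gain = round(inc$delta_qaly, 2),
    dominance = inc$dominance
  )
  written <- write_outputs(out_dir, list(
    "strategies.csv" = outcomes,
    "incremental.csv" = as.data.frame(inc),
    "headline.json" = headline
  ))
  write_manifest(out_dir, "scenario", config, NA_integer_, written)
  list(outcomes = outcomes, incremental = inc, headline = headline)
}

#' Probabilistic sensitivity analysis run with file outputs
#'
#' Wraps [psa_run()] and writes draw-level points (cost-effectiveness plane
#' coordinates), the quadrant summary and the acceptability curve as CSV.
#'
#' @inheritParams run_base_case
#' @param n Number of Monte Carlo draws.
#' @param seed Integer seed.
#' @param scenario `"oxmis"` or `"sequential"`.
#' @param ... Further arguments passed to [psa_run()].
#' @return The `psa_result`.
#' @export
run_psa <- function(config = NULL, n = 10000, seed = 1,
                    scenario = c("oxmis", "sequential"), out_dir = NULL,
                    ...) {
  params <- load_parameters(config)
  scenario <- match.arg(scenario)
  res <- psa_run(params, n = n, seed = seed, scenario = scenario, ...)
  summary_df <- data.frame(
    n_draws = res$n_draws, seed = res$seed, scenario = res$scenario,
    prop_cost_saving = res$prop_cost_saving,
    prop_dominant = res$prop_dominant, prop_sw = res$prop_sw,
    prop_ne = res$prop_ne, prop_inferior = res$prop_inferior,
    mean_delta_cost = res$mean_delta_cost,
    mean_delta_qaly = res$mean_delta_qaly,
    ci_delta_cost_low = res$ci_delta_cost[1],
    ci_delta_cost_high = res$ci_delta_cost[2],
    n_rejected = res$n_rejected
  )
  written <- write_outputs(out_dir, list(
    "psa_draws.csv" = res$draws,
    "psa_summary.csv" = summary_df,
    "ceac.csv" = res$ceac
  ))
  write_manifest(out_dir, "psa", config, seed, written)
  res
}

#' One-way (tornado) sensitivity analysis run with file outputs
#'
#' @inheritParams run_psa
#' @param ranges Named list of `c(low, high)` ranges; defaults to +/- 25%
#'   of base case on the six varied parameters.
#' @return The `tornado` data frame.
#' @export
run_tornado <- function(config = NULL, ranges = NULL, out_dir = NULL,
                        scenario = c("oxmis", "sequential")) {
  params <- load_parameters(config)
  scenario <- match.arg(scenario)
  if (is.null(ranges)) ranges <- default_one_way_ranges(params)
  rows <- one_way_sa(params, ranges, scenario = scenario)
  written <- write_outputs(out_dir, list("tornado.csv" = rows))
  write_manifest(out_dir, "tornado", config, NA_integer_, written)
  rows
}

#' Microsimulation run with file outputs
#'
#' Simulates patient-level cohorts for the OxMIS, clinical and sequential
#' arms and compares cohort means with the analytic tree expectations.
#'
#' @inheritParams run_psa
#' @param n Patients per arm.
#' @return A list with the per-arm cohort summaries (`summaries` data frame,
#'   including analytic expectations side by side) and the cohorts
#'   themselves.
#' @export
run_microsim <- function(config = NULL, n = 200000, seed = 1,
                         out_dir = NULL) {
  params <- load_parameters(config)
  specs <- list(oxmis = make_oxmis_strategy(params),
                clinical = make_clinical_strategy(params),
                sequential = make_sequential_strategy(params))
  cohorts <- list()
  rows <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    cohort <- simulate_cohort(spec, n = n, seed = seed + i - 1)
    s <- summarize_cohort(cohort)
    a <- evaluate_strategy(spec)
    rows[[i]] <- data.frame(
      strategy = s$name, n = s$n,
      sim_mean_cost = s$expected_cost, se_cost = s$se_cost,
      analytic_cost = a$expected_cost,
      sim_mean_qaly = s$expected_qaly, se_qaly = s$se_qaly,
      analytic_qaly = a$expected_qaly,
      sim_p_suicide = s$p_suicide, se_p_suicide = s$se_p_suicide,
      analytic_p_suicide = a$p_suicide,
      stringsAsFactors = FALSE
    )
    cohorts[[spec$name]] <- cohort
  }
  summaries <- do.call(rbind, rows)
  written <- write_outputs(out_dir, c(
    list("microsim_summary.csv" = summaries),
    stats::setNames(cohorts, paste0("cohort_", names(cohorts), ".csv"))
  ))
  write_manifest(out_dir, "microsim", config, seed, written)
  list(summaries = summaries, cohorts = cohorts)
}
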