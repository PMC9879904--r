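#' Distribution specification for a varied parameter
#'
#' Declares how one model parameter is perturbed in probabilistic
#' sensitivity analysis: a beta distribution for quantities on `[0, 1]`
#' (probabilities, the utility decrement), a gamma distribution for
#' non-negative quantities (costs), or a degenerate point mass (`fixed`).
#' The distribution is parameterised by its mean and standard deviation via
#' [moment_match()].
#'
#' @param parameter Name of the parameter (a [parameter_set()] field).
#' @param family One of `"beta"`, `"gamma"`, `"fixed"`.
#' @param mean Distribution mean, in the parameter's units.
#' @param sd Standard deviation (same units); ignored for `fixed`.
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(parameter, family = c("beta", "gamma", "fixed"),
                      mean, sd = NULL) {
  family <- match.arg(family)
  if (!is.numeric(mean) || length(mean) != 1 || !is.finite(mean)) {
    stop("mean must be a single finite number", call. = FALSE)
  }
  if (family != "fixed") {
    if (is.null(sd) || !is.numeric(sd) || length(sd) != 1 ||
        !is.finite(sd) || sd <= 0) {
      stop("sd must be a single positive number for family '", family, "'",
           call. = FALSE)
    }
  }
  if (family == "beta" && (mean <= 0 || mean >= 1)) {
    stop("beta family requires a mean strictly inside (0, 1); got ", mean,
         call. = FALSE)
  }
  if (family == "gamma" && mean <= 0) {
    stop("gamma family requires a positive mean; got ", mean, call. = FALSE)
  }
  structure(list(parameter = parameter, family = family, mean = mean,
                 sd = if (family == "fixed") 0 else sd),
            class = "dist_spec")
}

#' Moment-match a distribution family to a mean and standard deviation
#'
#' Beta: with `nu = m(1-m)/s^2 - 1`, `alpha = m * nu` and
#' `beta = (1-m) * nu`; feasible only when `s^2 < m(1-m)`.
#' Gamma: `shape = (m/s)^2`, `scale = s^2/m`. Fixed: a point mass at the
#' mean.
#'
#' @param family `"beta"`, `"gamma"` or `"fixed"`.
#' @param mean,sd Target moments.
#' @return A list with `family` and the distribution parameters
#'   (`shape1`/`shape2` for beta, `shape`/`scale` for gamma, `value` for
#'   fixed).
#' @export
#' @examples
#' moment_match("gamma", 1615, 323) # shape 25, scale 64.6
moment_match <- function(family = c("beta", "gamma", "fixed"), mean,
                         sd = NULL) {
  family <- match.arg(family)
  if (family == "fixed") {
    return(list(family = "fixed", value = mean))
  }
  if (is.null(sd) || sd <= 0) {
    stop("sd must be positive for family '", family, "'", call. = FALSE)
  }
  if (family == "beta") {
    if (mean <= 0 || mean >= 1) {
      stop("beta mean must lie strictly inside (0, 1)", call. = FALSE)
    }
    if (sd^2 >= mean * (1 - mean)) {
      stop("infeasible beta variance: sd^2 = ", signif(sd^2, 6),
           " must be < mean*(1-mean) = ", signif(mean * (1 - mean), 6),
           call. = FALSE)
    }
    nu <- mean * (1 - mean) / sd^2 - 1
    return(list(family = "beta", shape1 = mean * nu,
                shape2 = (1 - mean) * nu))
  }
  list(family = "gamma", shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Draw samples from a distribution specification
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  mm <- moment_match(spec$family, spec$mean, if (spec$family == "fixed")
    NULL else spec$sd)
  switch(mm$family,
         beta = stats::rbeta(n, mm$shape1, mm$shape2),
         gamma = stats::rgamma(n, shape = mm$shape, scale = mm$scale),
         fixed = rep(mm$value, n))
}

#' Default PSA distribution specifications
#'
#' The six parameters varied in the probabilistic sensitivity analysis are
#' the cost of the OxMIS assessment, the cost of HRM, the cost of a suicide,
#' the HRM utility decrement, the probability of a high-risk OxMIS
#' assessment, and the suicide risk in the OxMIS high-risk stratum. Beta
#' distributions are used for the probabilities and the utility decrement,
#' gamma for the costs. Dispersions default to a coefficient of variation of
#' 0.2 (sd = 20% of the mean) for every varied parameter.
#'
#' @param params A validated [parameter_set()].
#' @param cv Coefficient of variation applied to every varied parameter.
#' @return A named list of [dist_spec()] objects.
#' @export
default_psa_specs <- function(params, cv = 0.2) {
  params <- validate_parameter_set(params)
  if (!is.numeric(cv) || length(cv) != 1 || cv <= 0) {
    stop("cv must be a single positive number", call. = FALSE)
  }
  mk <- function(name, family) {
    m <- params[[name]]
    dist_spec(name, family, mean = m, sd = cv * m)
  }
  specs <- list(
    mk("cost_oxmis", "gamma"),
    mk("cost_hrm", "gamma"),
    mk("cost_suicide", "gamma"),
    mk("utility_decrement_hrm", "beta"),
    mk("p_high_oxmis", "beta"),
    mk("p_suicide_high", "beta")
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "parameter"))
}

build_strategy_pair <- function(params, scenario, posttest) {
  comparator <- make_clinical_strategy(params)
  intervention <- switch(scenario,
                         oxmis = make_oxmis_strategy(params),
                         sequential = make_sequential_strategy(params,
                                                               posttest))
  list(intervention = intervention, comparator = comparator)
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' For each draw, samples all varied parameters jointly and independently
#' from their distributions, rebuilds both strategies of the selected
#' comparison, and records the incremental (cost, QALY) pair. Draws that
#' violate a model invariant (for example a drawn high-stratum risk below
#' the overall incidence, or an infeasible derived low-branch risk) are
#' rejected and resampled; the rejection count is returned. Identical seeds
#' give identical results.
#'
#' @param params A validated [parameter_set()]; unvaried parameters are held
#'   at these values.
#' @param specs Named list of [dist_spec()] objects, one per varied
#'   parameter; defaults to [default_psa_specs()].
#' @param n Number of accepted draws (the published analysis used 10000).
#' @param seed Integer seed.
#' @param scenario `"oxmis"` (OxMIS vs clinical judgment) or `"sequential"`
#'   (clinical-then-OxMIS vs clinical judgment).
#' @param posttest Post-test probability for the sequential scenario.
#' @param wtp Willingness-to-pay threshold used for the summary NMB.
#' @param ceac_thresholds Thresholds (GBP/QALY) at which the acceptability
#'   curve is evaluated.
#' @param max_attempts Hard cap on total sampling attempts, to surface
#'   miscalibrated specifications.
#' @return An object of class `psa_result`: `n_draws`, `seed`, `draws` (a
#'   data frame with one row per draw: the sampled parameters, `delta_cost`,
#'   `delta_qaly`, `quadrant`), quadrant proportions (`prop_dominant`,
#'   `prop_sw`, `prop_ne`, `prop_inferior`, `prop_cost_saving`), `ceac` (a
#'   data frame of threshold and probability cost-effective) and
#'   `n_rejected`.
#' @export
psa_run <- function(params, specs = default_psa_specs(params), n = 10000,
                    seed = 1, scenario = c("oxmis", "sequential"),
                    posttest = 0.69, wtp = params$wtp_threshold,
                    ceac_thresholds = seq(0, 50000, by = 2500),
                    max_attempts = 1e6) {
  params <- validate_parameter_set(params)
  scenario <- match.arg(scenario)
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot(length(specs) >= 1, !is.null(names(specs)),
            all(vapply(specs, inherits, TRUE, "dist_spec")))
  set.seed(seed)

  varied <- names(specs)
  samples <- matrix(NA_real_, nrow = n, ncol = length(varied),
                    dimnames = list(NULL, varied))
  delta_cost <- numeric(n)
  delta_qaly <- numeric(n)
  n_rejected <- 0L
  attempts <- 0L

  for (i in seq_len(n)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("PSA exceeded ", max_attempts, " sampling attempts; the ",
             "distribution specifications are likely miscalibrated",
             call. = FALSE)
      }
      draw <- vapply(specs, sample_dist, numeric(1), n = 1)
      trial <- unclass(params)
      trial[varied] <- as.list(draw)
      pair <- tryCatch(
        build_strategy_pair(validate_parameter_set(trial), scenario,
                            posttest),
        error = function(e) NULL
      )
      if (!is.null(pair)) break
      n_rejected <- n_rejected + 1L
    }
    samples[i, ] <- draw
    oi <- evaluate_strategy(pair$intervention)
    oc <- evaluate_strategy(pair$comparator)
    delta_cost[i] <- oi$expected_cost - oc$expected_cost
    delta_qaly[i] <- oi$expected_qaly - oc$expected_qaly
  }

  quadrant <- ce_quadrant(delta_cost, delta_qaly)
  draws <- data.frame(draw = seq_len(n), samples, delta_cost = delta_cost,
                      delta_qaly = delta_qaly, quadrant = quadrant,
                      stringsAsFactors = FALSE)
  ceac <- data.frame(
    threshold = ceac_thresholds,
    prob_cost_effective = vapply(ceac_thresholds, function(lambda) {
      mean(lambda * delta_qaly - delta_cost > 0)
    }, numeric(1))
  )
  structure(
    list(
      n_draws = n,
      seed = seed,
      scenario = scenario,
      draws = draws,
      prop_dominant = mean(quadrant == "SE"),
      prop_sw = mean(quadrant == "SW"),
      prop_ne = mean(quadrant == "NE"),
      prop_inferior = mean(quadrant == "NW"),
      prop_cost_saving = mean(delta_cost < 0),
      mean_delta_cost = mean(delta_cost),
      mean_delta_qaly = mean(delta_qaly),
      ci_delta_cost = unname(stats::quantile(delta_cost, c(0.025, 0.975))),
      ci_delta_qaly = unname(stats::quantile(delta_qaly, c(0.025, 0.975))),
      nmb = wtp * mean(delta_qaly) - mean(delta_cost),
      wtp = wtp,
      ceac = ceac,
      n_rejected = n_rejected
    ),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA (%s vs clinical): %d draws, seed %d, %d rejected\n",
              x$scenario, x$n_draws, x$seed, x$n_rejected))
  cat(sprintf("  mean delta cost £%.1f (95%% CI %.1f; %.1f), mean delta QALYs %.4f\n",
              x$mean_delta_cost, x$ci_delta_cost[1], x$ci_delta_cost[2],
              x$mean_delta_qaly))
  cat(sprintf("  cost-saving: %.2f%%; dominant (SE): %.1f%%; cheaper-but-less-effective (SW): %.1f%%; inferior (NW): %.1f%%; NE: %.1f%%\n",
              100 * x$prop_cost_saving, 100 * x$prop_dominant,
              100 * x$prop_sw, 100 * x$prop_inferior, 100 * x$prop_ne))
  invisible(x)
}

#' Default one-way sensitivity ranges
#'
#' Low/high values at +/- 25% of the base case for each of the six varied
#' parameters, truncated to the parameter's domain.
#'
#' @param params A validated [parameter_set()].
#' @param rel Relative half-width of the range (default 0.25).
#' @return A named list of `c(low, high)` pairs.
#' @export
default_one_way_ranges <- function(params, rel = 0.25) {
  params <- validate_parameter_set(params)
  varied <- c("cost_oxmis", "cost_hrm", "cost_suicide",
              "utility_decrement_hrm", "p_high_oxmis", "p_suicide_high")
  bounded <- c("utility_decrement_hrm", "p_high_oxmis", "p_suicide_high")
  out <- lapply(varied, function(name) {
    base <- params[[name]]
    lo <- base * (1 - rel)
    hi <- base * (1 + rel)
    if (name %in% bounded) hi <- min(hi, 1)
    c(low = max(lo, 0), high = hi)
  })
  stats::setNames(out, varied)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter is set in turn to the low and then the high end of its
#' range, all other parameters held at base case; both strategies are
#' re-evaluated and the ICER recorded at each end. Rows are sorted by
#' descending span (absolute difference between the two ICERs), the order a
#' tornado diagram plots.
#'
#' @param params A validated [parameter_set()].
#' @param ranges Named list mapping parameter name to `c(low, high)`;
#'   defaults to [default_one_way_ranges()].
#' @param scenario,posttest Comparison selector as in [psa_run()].
#' @return A data frame of class `tornado` with columns `parameter`,
#'   `low_value`, `high_value`, `icer_at_low`, `icer_at_high`,
#'   `quadrant_at_low`, `quadrant_at_high` and `span`.
#' @export
one_way_sa <- function(params, ranges = default_one_way_ranges(params),
                       scenario = c("oxmis", "sequential"),
                       posttest = 0.69) {
  params <- validate_parameter_set(params)
  scenario <- match.arg(scenario)
  stopifnot(length(ranges) >= 1, !is.null(names(ranges)))

  eval_at <- function(name, value) {
    trial <- unclass(params)
    trial[[name]] <- value
    trial <- tryCatch(validate_parameter_set(trial), error = function(e) {
      stop("range for parameter '", name, "' violates a model invariant: ",
           conditionMessage(e), call. = FALSE)
    })
    pair <- build_strategy_pair(trial, scenario, posttest)
    incremental(evaluate_strategy(pair$intervention),
                evaluate_strategy(pair$comparator),
                wtp = params$wtp_threshold)
  }

  rows <- lapply(names(ranges), function(name) {
    rng <- ranges[[name]]
    if (length(rng) != 2 || any(!is.finite(rng)) || rng[1] > rng[2]) {
      stop("range for parameter '", name,
           "' must be a finite pair (low, high) with low <= high",
           call. = FALSE)
    }
    lo <- eval_at(name, rng[[1]])
    hi <- eval_at(name, rng[[2]])
    data.frame(parameter = name, low_value = rng[[1]],
               high_value = rng[[2]], icer_at_low = lo$icer,
               icer_at_high = hi$icer, quadrant_at_low = lo$quadrant,
               quadrant_at_high = hi$quadrant,
               span = abs(hi$icer - lo$icer), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}
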