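#' Classify a cost-effectiveness plane quadrant
#'
#' The plane has incremental QALYs on the x axis and incremental cost on the
#' y axis. NE: dearer and more effective; NW: dearer and less effective
#' (intervention dominated); SE: cheaper and more effective (intervention
#' dominant); SW: cheaper and less effective. Points on an axis are assigned
#' to the adjacent quadrant that preserves the cost sign (ties in QALYs
#' count as "not more effective").
#'
#' @param delta_cost Incremental cost (intervention minus comparator), GBP.
#' @param delta_qaly Incremental QALYs.
#' @return Character vector of quadrant labels among `"NE"`, `"NW"`, `"SE"`,
#'   `"SW"`.
#' @export
ce_quadrant <- function(delta_cost, delta_qaly) {
  ifelse(delta_cost < 0,
         ifelse(delta_qaly > 0, "SE", "SW"),
         ifelse(delta_qaly > 0, "NE", "NW"))
}

dominance_label <- function(delta_cost, delta_qaly) {
  if (delta_cost < 0 && delta_qaly > 0) {
    "intervention dominant"
  } else if (delta_cost > 0 && delta_qaly < 0) {
    "comparator dominant"
  } else if (delta_cost == 0 && delta_qaly == 0) {
    "indifferent"
  } else if (delta_cost >= 0) {
    "trade-off NE"
  } else {
    "trade-off SW"
  }
}

#' Incremental cost-effectiveness of one strategy against another
#'
#' Computes the incremental cost and QALYs of the intervention versus the
#' comparator, the ICER (undefined when the QALY difference is zero), the
#' cost-effectiveness plane quadrant, a dominance classification, and the
#' net monetary benefit `wtp * delta_qaly - delta_cost`. Because a bare
#' negative ICER is ambiguous (it arises in both the dominant and the
#' dominated quadrant), the ICER is always reported together with its
#' quadrant.
#'
#' @param intervention,comparator `strategy_outcome` objects from
#'   [evaluate_strategy()] (or [summarize_cohort()]), evaluated under the
#'   same parameter set.
#' @param wtp Willingness-to-pay threshold, GBP per QALY (default 20000).
#' @return An object of class `incremental_result` with fields
#'   `intervention`, `comparator`, `delta_cost`, `delta_qaly`, `icer`
#'   (`NA` when `delta_qaly == 0`), `quadrant`, `dominance`, `nmb` and
#'   `wtp`.
#' @export
#' @examples
#' params <- parameter_set()
#' incremental(evaluate_strategy(make_oxmis_strategy(params)),
#'             evaluate_strategy(make_clinical_strategy(params)))
incremental <- function(intervention, comparator, wtp = 20000) {
  stopifnot(inherits(intervention, "strategy_outcome"),
            inherits(comparator, "strategy_outcome"))
  if (!is.numeric(wtp) || length(wtp) != 1 || !is.finite(wtp) || wtp < 0) {
    stop("wtp must be a single non-negative number", call. = FALSE)
  }
  delta_cost <- intervention$expected_cost - comparator$expected_cost
  delta_qaly <- intervention$expected_qaly - comparator$expected_qaly
  icer <- if (delta_qaly == 0) NA_real_ else delta_cost / delta_qaly
  structure(
    list(
      intervention = intervention$name,
      comparator = comparator$name,
      delta_cost = delta_cost,
      delta_qaly = delta_qaly,
      icer = icer,
      quadrant = ce_quadrant(delta_cost, delta_qaly),
      dominance = dominance_label(delta_cost, delta_qaly),
      nmb = wtp * delta_qaly - delta_cost,
      wtp = wtp
    ),
    class = "incremental_result"
  )
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("Incremental analysis: %s vs %s\n", x$intervention,
              x$comparator))
  cat(sprintf("  delta cost:  £%.2f\n", x$delta_cost))
  cat(sprintf("  delta QALYs: %.5f\n", x$delta_qaly))
  if (is.na(x$icer)) {
    cat("  ICER: undefined (zero QALY difference)\n")
  } else {
    cat(sprintf("  ICER: £%.0f per QALY (quadrant %s)\n", x$icer,
                x$quadrant))
  }
  cat(sprintf("  classification: %s\n", x$dominance))
  cat(sprintf("  NMB at £%.0f/QALY: £%.2f\n", x$wtp, x$nmb))
  invisible(x)
}

#' @export
as.data.frame.incremental_result <- function(x, ...) {
  data.frame(intervention = x$intervention, comparator = x$comparator,
             delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
             icer = x$icer, quadrant = x$quadrant, dominance = x$dominance,
             nmb = x$nmb, wtp = x$wtp, stringsAsFactors = FALSE)
}
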