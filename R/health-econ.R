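# Economic outcome computation: ICER with dominance classification, mRS
# change summaries, and population-level scaling. ICERs are always computed
# from full-precision increments; rounding happens only at the presentation
# layer (render_report).

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Classifies the incremental (cost, QALY) pair over the four sign
#' quadrants: a strategy that gains QALYs while saving costs is *dominant*
#' (no ICER reported); one that loses QALYs at extra cost is *dominated*;
#' when the signs agree the ICER `inc_cost / inc_qalys` is reported. Zero
#' incremental QALYs with non-zero cost has no defined ICER.
#'
#' @param inc_cost incremental cost in euros (scenario minus baseline).
#' @param inc_qalys incremental QALYs.
#' @return A list of class `icer` with `status` (one of `"icer"`,
#'   `"dominant"`, `"dominated"`, `"undefined"`, `"no_difference"`) and
#'   `value` (numeric ICER when `status == "icer"`, otherwise `NA`).
#' @examples
#' icer(-220.20, 0.0297) # dominant
#' icer(100, 0.05)       # 2000 euros per QALY
#' @export
icer <- function(inc_cost, inc_qalys) {
  check_number(inc_cost, "inc_cost")
  check_number(inc_qalys, "inc_qalys")
  res <- if (inc_qalys == 0) {
    if (inc_cost == 0) list(status = "no_difference", value = NA_real_)
    else list(status = "undefined", value = NA_real_)
  } else if (inc_qalys > 0 && inc_cost < 0) {
    list(status = "dominant", value = NA_real_)
  } else if (inc_qalys < 0 && inc_cost > 0) {
    list(status = "dominated", value = NA_real_)
  } else {
    list(status = "icer", value = inc_cost / inc_qalys)
  }
  structure(c(res, list(inc_cost = inc_cost, inc_qalys = inc_qalys)),
            class = "icer")
}

#' @export
print.icer <- function(x, ...) {
  cat(format_icer(x), "\n")
  invisible(x)
}

#' Render an ICER for display
#' @param x an [icer()] object.
#' @return A character scalar (`"Dominant"`, `"Dominated"`, a euro/QALY
#'   figure, or `"undefined"`).
#' @export
format_icer <- function(x) {
  switch(x$status,
         dominant = "Dominant",
         dominated = "Dominated",
         no_difference = "No difference",
         undefined = "Undefined",
         icer = sprintf("%.2f", x$value))
}

#' Percentage-point mRS change summary
#'
#' Per-bin difference `(scenario - baseline) * 100`, in percentage points.
#' Rate targets are summarised at cohort scope; time targets at the scope of
#' the treated arm (the convention under which the per-minute effect shows
#' up undiluted by the arm share).
#'
#' @param baseline,scenario [mrs_distribution()] objects of matching scope.
#' @param scope `"cohort"` or `"treated-arm"`; if either distribution
#'   carries a `scope` attribute it must match.
#' @return Named numeric vector (`mrs02`, `mrs35`, `mrs6`) of
#'   percentage-point changes with a `scope` attribute; bins sum to 0.
#' @export
mrs_change_summary <- function(baseline, scenario,
                               scope = c("cohort", "treated-arm")) {
  scope <- match.arg(scope)
  for (d in list(baseline, scenario)) {
    s <- attr(d, "scope")
    if (!is.null(s) && !identical(s, scope)) {
      stopf("distribution scope '%s' does not match requested scope '%s'",
            s, scope)
    }
  }
  baseline <- as_mrs_distribution(baseline)
  scenario <- as_mrs_distribution(scenario)
  delta <- (unclass(scenario) - unclass(baseline)) * 100
  structure(c(mrs02 = delta[["p_mrs02"]], mrs35 = delta[["p_mrs35"]],
              mrs6 = delta[["p_mrs6"]]),
            scope = scope, class = "mrs_change")
}

#' Scale per-patient results to an annual national cohort
#'
#' @param per_patient a list-like with `inc_cost` and `inc_qalys` fields
#'   (e.g. the `econ` component of [run_comparison()] or an [icer()]).
#' @param addressable number of addressable patients per year; what counts
#'   as addressable (all incident AIS vs the treated subgroup) is the
#'   caller's choice and is passed explicitly.
#' @return A list of class `population_result` with
#'   `population_inc_cost`, `population_inc_qalys` and `addressable`.
#' @export
population_scale <- function(per_patient, addressable) {
  check_number(addressable, "addressable", 0)
  inc_cost <- per_patient$inc_cost
  inc_qalys <- per_patient$inc_qalys
  if (is.null(inc_cost) || is.null(inc_qalys)) {
    stopf("per_patient must carry inc_cost and inc_qalys")
  }
  structure(list(population_inc_cost = inc_cost * addressable,
                 population_inc_qalys = inc_qalys * addressable,
                 addressable = addressable),
            class = "population_result")
}
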