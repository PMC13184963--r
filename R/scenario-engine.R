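# The six care-improvement targets as transformations of a country
# configuration, and the baseline-vs-target comparison pipeline.
#
# Targets 1-4 are absolute (skipped where the baseline already meets them);
# Targets 5-6 are relative and always apply. Exactly one parameter family
# differs between the baseline and scenario runs.

#' Specification of one care-improvement target
#'
#' @param target_id integer 1-6:
#'   1 raise the IVT rate, 2 raise the EVT rate, 3 reduce onset-to-needle
#'   time, 4 reduce onset-to-puncture time, 5 reduce recurrent-stroke
#'   incidence, 6 reduce first-time stroke incidence.
#' @param ivt_target_rate,evt_target_rate target treatment rates
#'   (defaults 0.15 and 0.05).
#' @param otn_threshold,otp_threshold strict time thresholds in minutes
#'   (defaults 120 and 200).
#' @param recurrence_reduction,incidence_reduction relative reductions in
#'   \[0, 1\] (defaults 0.10).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(target_id,
                          ivt_target_rate = 0.15, evt_target_rate = 0.05,
                          otn_threshold = 120, otp_threshold = 200,
                          recurrence_reduction = 0.10,
                          incidence_reduction = 0.10) {
  target_id <- as.integer(check_number(target_id, "target_id", 1, 6))
  structure(list(
    target_id = target_id,
    ivt_target_rate = check_probability(ivt_target_rate, "ivt_target_rate"),
    evt_target_rate = check_probability(evt_target_rate, "evt_target_rate"),
    otn_threshold = check_number(otn_threshold, "otn_threshold", 0, Inf,
                                 strict_lower = TRUE),
    otp_threshold = check_number(otp_threshold, "otp_threshold", 0, Inf,
                                 strict_lower = TRUE),
    recurrence_reduction = check_probability(recurrence_reduction,
                                             "recurrence_reduction"),
    incidence_reduction = check_probability(incidence_reduction,
                                            "incidence_reduction")
  ), class = "scenario_spec")
}

#' Human-readable target label
#' @param target_id integer 1-6.
#' @return Character scalar.
#' @export
target_label <- function(target_id) {
  c("Increase IVT rate", "Increase EVT rate",
    "Reduce onset-to-needle time", "Reduce onset-to-puncture time",
    "Reduce recurrent stroke incidence",
    "Reduce first-time stroke incidence")[target_id]
}

#' Is an absolute target already met at baseline?
#'
#' Rate targets are met when the baseline rate reaches the target level;
#' time targets when the baseline time is strictly below the threshold.
#' Relative targets (5-6) are never "met".
#'
#' @param config a [country_config()].
#' @param spec a [scenario_spec()].
#' @return Logical scalar.
#' @export
target_is_met <- function(config, spec) {
  p <- config$profile
  switch(spec$target_id,
         p$ivt_rate >= spec$ivt_target_rate - 1e-12,
         p$evt_rate >= spec$evt_target_rate - 1e-12,
         p$otn_minutes < spec$otn_threshold,
         p$otp_minutes < spec$otp_threshold,
         FALSE,
         FALSE)
}

#' Transform model inputs to meet a target
#'
#' Applies the target's parameter change while leaving every other input
#' untouched. Rate targets shift cohort share from standard care into the
#' reperfusion arm; time targets shift the treated arm's 90-day outcome
#' distribution via the per-minute effect and the mortality odds ratio
#' (with the country's onset-to-puncture OR override where set); Target 5
#' multiplies every recurrence probability by `1 - recurrence_reduction`;
#' Target 6 leaves the stroke model untouched and instead routes a fraction
#' of the cohort down the general-population pathway.
#'
#' @param config a [country_config()].
#' @param spec a [scenario_spec()].
#' @return A list of class `scenario_application`: `config` (transformed),
#'   `met_already`, `general_fraction` (non-zero only for Target 6),
#'   `minutes_saved` (time targets) and `target_id`.
#' @export
apply_target <- function(config, spec) {
  stopifnot(inherits(config, "country_config"),
            inherits(spec, "scenario_spec"))
  met <- target_is_met(config, spec)
  out <- list(config = config, met_already = met, general_fraction = 0,
              minutes_saved = 0, target_id = spec$target_id)
  if (met) {
    return(structure(out, class = "scenario_application"))
  }
  cfg <- config
  if (spec$target_id == 1L) {
    cfg$profile <- apply_rate_shift(cfg$profile, "ivt", spec$ivt_target_rate)
  } else if (spec$target_id == 2L) {
    cfg$profile <- apply_rate_shift(cfg$profile, "evt", spec$evt_target_rate)
  } else if (spec$target_id == 3L) {
    saved <- minutes_saved(cfg$profile$otn_minutes, spec$otn_threshold)
    cfg$outcomes$ivt <- apply_time_effect(cfg$outcomes$ivt, saved,
                                          cfg$acute_effects,
                                          use_otp_override = FALSE)
    cfg$profile$otn_minutes <- cfg$profile$otn_minutes - saved
    out$minutes_saved <- saved
  } else if (spec$target_id == 4L) {
    saved <- minutes_saved(cfg$profile$otp_minutes, spec$otp_threshold)
    cfg$outcomes$evt <- apply_time_effect(cfg$outcomes$evt, saved,
                                          cfg$acute_effects,
                                          use_otp_override = TRUE)
    cfg$profile$otp_minutes <- cfg$profile$otp_minutes - saved
    out$minutes_saved <- saved
  } else if (spec$target_id == 5L) {
    f <- 1 - spec$recurrence_reduction
    rec <- config$transitions$recurrence
    cfg$transitions$recurrence <- recurrence_schedule(
      p_year1 = rec$p_year1 * f, p_years2_5 = rec$p_years2_5 * f,
      p_years6_10 = rec$p_years6_10 * f, p_beyond10 = rec$p_beyond10 * f)
  } else if (spec$target_id == 6L) {
    out$general_fraction <- spec$incidence_reduction
  }
  out$config <- cfg
  structure(out, class = "scenario_application")
}

# One arm of the model: decision tree + Markov projection for a config.
run_pathway <- function(config, reset_clock = FALSE) {
  mix <- arm_mix_from_profile(config$profile)
  dist90 <- mix_90day_distribution(mix, config$outcomes)
  m <- config$costs$acute_cost_by_arm_and_band
  arm_dists <- config$outcomes
  acute_cost <- sum(vapply(TREATMENT_ARMS, function(a) {
    mix[[a]] * sum(unclass(arm_dists[[a]]) * m[a, ])
  }, numeric(1)))
  trace <- run_cohort(dist90, config, reset_clock = reset_clock)
  lifetime <- accumulate_outcomes(trace, config$utilities, config$costs,
                                  config$discount_rate)
  list(dist90 = dist90, acute_cost = acute_cost, trace = trace,
       lifetime = lifetime,
       total_cost = acute_cost + lifetime$total_cost,
       total_qalys = lifetime$total_qalys,
       life_years = lifetime$life_years,
       arm_dists = arm_dists)
}

#' Lifetime outcomes of the general-population pathway
#'
#' Members face only background life-table mortality from the cohort start
#' age, accrue the general-population utility and zero stroke costs. Used by
#' the primary-prevention target (Target 6). Cycle conventions (full first
#' year, end-of-cycle discounting, life-table closure) match the stroke
#' Markov model.
#'
#' @param config a [country_config()].
#' @return A list of class `lifetime_result`.
#' @export
general_population_path <- function(config) {
  stopifnot(inherits(config, "country_config"))
  lt <- config$life_table
  start_age <- config$cohort_start_age
  r <- config$discount_rate
  u <- config$utilities$u_general_population
  n_cycles <- as.integer(lt$max_age - floor(start_age) + 1)
  surv <- 1
  qaly <- qaly_u <- ly <- ly_u <- 0
  for (t in seq_len(n_cycles)) {
    disc <- (1 + r)^(-t)
    qaly <- qaly + disc * surv * u
    qaly_u <- qaly_u + surv * u
    ly <- ly + disc * surv
    ly_u <- ly_u + surv
    surv <- surv * (1 - qx_at(lt, start_age + t - 1))
  }
  structure(list(total_cost = 0, total_qalys = qaly, life_years = ly,
                 undiscounted = list(total_cost = 0, total_qalys = qaly_u,
                                     life_years = ly_u),
                 cycle_costs = NULL, cycle_qalys = NULL),
            class = "lifetime_result")
}

#' Run a baseline-vs-target comparison for one country
#'
#' Runs the decision tree plus Markov pipeline for the baseline and the
#' target-transformed inputs with identical numerics elsewhere, and derives
#' the incremental economics. Deterministic for fixed inputs. For Target 6
#' the scenario population is the exact mixture
#' `(1 - r) * stroke path + r * general-population path` with the total
#' cohort size maintained.
#'
#' @param config a [country_config()].
#' @param spec a [scenario_spec()].
#' @param reset_clock recurrence-clock convention, see [run_cohort()].
#' @return A list of class `scenario_result`: `baseline` and `scenario`
#'   pathway summaries (90-day distribution, acute cost, lifetime result,
#'   totals), `met_already`, and `econ` holding `inc_cost`, `inc_qalys`,
#'   `icer`, `mrs02_change_pp`, `mrs35_change_pp` and `scope`.
#' @export
run_comparison <- function(config, spec, reset_clock = FALSE) {
  app <- apply_target(config, spec)
  base <- run_pathway(config, reset_clock = reset_clock)

  if (app$met_already) {
    scen <- base
  } else if (spec$target_id == 6L) {
    gen <- general_population_path(config)
    r <- app$general_fraction
    scen <- base
    scen$total_cost <- (1 - r) * base$total_cost + r * gen$total_cost
    scen$total_qalys <- (1 - r) * base$total_qalys + r * gen$total_qalys
    scen$life_years <- (1 - r) * base$life_years + r * gen$life_years
    scen$acute_cost <- (1 - r) * base$acute_cost
    scen$general_path <- gen
  } else {
    scen <- run_pathway(app$config, reset_clock = reset_clock)
  }

  scope <- if (spec$target_id %in% c(3L, 4L)) "treated-arm" else "cohort"
  if (scope == "cohort") {
    mrs_change <- mrs_change_summary(base$dist90, scen$dist90, "cohort")
  } else {
    arm <- if (spec$target_id == 3L) "ivt" else "evt"
    mrs_change <- mrs_change_summary(base$arm_dists[[arm]],
                                     scen$arm_dists[[arm]], "treated-arm")
  }

  inc_cost <- scen$total_cost - base$total_cost
  inc_qalys <- scen$total_qalys - base$total_qalys
  econ <- list(inc_cost = inc_cost, inc_qalys = inc_qalys,
               icer = icer(inc_cost, inc_qalys),
               mrs02_change_pp = mrs_change[["mrs02"]],
               mrs35_change_pp = mrs_change[["mrs35"]],
               scope = scope)
  structure(list(country = config$name, spec = spec, baseline = base,
                 scenario = scen, met_already = app$met_already,
                 minutes_saved = app$minutes_saved, econ = econ),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result: %s, target %d (%s)>\n", x$country,
              x$spec$target_id, target_label(x$spec$target_id)))
  if (x$met_already) {
    cat("  target already met at baseline; no incremental outcomes\n")
    return(invisible(x))
  }
  cat(sprintf("  incremental cost:  %10.2f EUR\n", x$econ$inc_cost))
  cat(sprintf("  incremental QALYs: %10.4f\n", x$econ$inc_qalys))
  cat(sprintf("  ICER:              %s\n", format_icer(x$econ$icer)))
  cat(sprintf("  mRS 0-2 change:    %+.2f pp (%s scope)\n",
              x$econ$mrs02_change_pp, x$econ$scope))
  invisible(x)
}
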