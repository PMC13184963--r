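# Domain types for the stroke care model. All constructors validate their
# invariants eagerly so that a built object is a valid object; load_config()
# funnels raw file content through these same constructors.

MRS_BANDS <- c("p_mrs02", "p_mrs35", "p_mrs6")
TREATMENT_ARMS <- c("standard", "ivt", "evt")
MARKOV_STATES <- c("mrs02", "mrs35", "recurrent", "dead")

#' 90-day functional outcome distribution over mRS bands
#'
#' Three-bin simplex over modified Rankin Scale bands at 90 days:
#' mRS 0-2 (functionally independent), mRS 3-5 (functionally dependent) and
#' mRS 6 (dead).
#'
#' @param p_mrs02,p_mrs35,p_mrs6 band probabilities; each in \[0, 1\] and
#'   summing to 1 (tolerance 1e-6).
#' @return A named numeric vector of class `mrs_distribution`.
#' @examples
#' mrs_distribution(0.22, 0.55, 0.23) # standard medical care at 90 days
#' @export
mrs_distribution <- function(p_mrs02, p_mrs35, p_mrs6) {
  x <- c(p_mrs02 = check_probability(p_mrs02, "p_mrs02"),
         p_mrs35 = check_probability(p_mrs35, "p_mrs35"),
         p_mrs6 = check_probability(p_mrs6, "p_mrs6"))
  s <- sum(x)
  if (abs(s - 1) > 1e-6) {
    stopf("mRS band probabilities must sum to 1; got sum %.10g", s)
  }
  structure(x, class = "mrs_distribution")
}

as_mrs_distribution <- function(x) {
  if (inherits(x, "mrs_distribution")) return(x)
  if (is.list(x)) x <- unlist(x)
  if (length(x) != 3L) stopf("an mRS distribution needs exactly 3 bands")
  if (!is.null(names(x)) && all(MRS_BANDS %in% names(x))) x <- x[MRS_BANDS]
  mrs_distribution(x[[1L]], x[[2L]], x[[3L]])
}

#' @export
print.mrs_distribution <- function(x, ...) {
  cat(sprintf("<mRS distribution>  0-2: %.4f   3-5: %.4f   6: %.4f\n",
              x[["p_mrs02"]], x[["p_mrs35"]], x[["p_mrs6"]]))
  invisible(x)
}

#' 90-day outcome table per treatment arm
#'
#' Holds one [mrs_distribution()] for each treatment strategy of the acute
#' decision tree: standard medical care, IVT and EVT.
#'
#' @param standard,ivt,evt `mrs_distribution` objects (anything coercible).
#' @return A list of class `outcome_table`.
#' @export
outcome_table <- function(standard, ivt, evt) {
  structure(list(standard = as_mrs_distribution(standard),
                 ivt = as_mrs_distribution(ivt),
                 evt = as_mrs_distribution(evt)),
            class = "outcome_table")
}

#' National treatment profile
#'
#' Baseline national performance: reperfusion treatment rates and
#' representative onset-to-treatment times.
#'
#' @param ivt_rate,evt_rate fractions of the incident AIS cohort receiving
#'   IVT alone and EVT; the remainder receives standard medical care.
#' @param otn_minutes onset-to-needle time (IVT), minutes.
#' @param otp_minutes onset-to-puncture time (EVT), minutes.
#' @return A list of class `treatment_profile`.
#' @export
treatment_profile <- function(ivt_rate, evt_rate, otn_minutes, otp_minutes) {
  ivt_rate <- check_probability(ivt_rate, "ivt_rate")
  evt_rate <- check_probability(evt_rate, "evt_rate")
  if (ivt_rate + evt_rate > 1 + 1e-9) {
    stopf("ivt_rate + evt_rate must not exceed 1 (got %.10g)",
          ivt_rate + evt_rate)
  }
  structure(list(
    ivt_rate = ivt_rate,
    evt_rate = evt_rate,
    otn_minutes = check_number(otn_minutes, "otn_minutes", 0, Inf,
                               strict_lower = TRUE),
    otp_minutes = check_number(otp_minutes, "otp_minutes", 0, Inf,
                               strict_lower = TRUE)
  ), class = "treatment_profile")
}

#' Share of the cohort on standard medical care
#' @param profile a [treatment_profile()].
#' @return Fraction of the cohort receiving neither IVT nor EVT.
#' @export
standard_care_share <- function(profile) {
  1 - profile$ivt_rate - profile$evt_rate
}

#' Acute treatment-effect parameters
#'
#' Effect operators for earlier treatment: a linear absolute risk difference
#' (ARD) on the mRS 0-2 proportion per minute saved, and an odds ratio of
#' 90-day mortality per hour of treatment delay.
#'
#' @param ard_per_minute increase in the mRS 0-2 proportion per minute of
#'   earlier treatment (default 0.0008, i.e. 4.8 percentage points per hour).
#' @param mortality_or_per_hour odds ratio of 90-day mortality per 1-hour
#'   delay (default 1.16; 95% CI 1.05-1.28).
#' @param otp_or_override optional country-specific mortality OR used for
#'   onset-to-puncture effects (set to 1 where the OR at long onset-to-groin
#'   times is not supported, as for the United Kingdom).
#' @param mortality_rule how the mortality OR is applied to the 90-day death
#'   probability: `"odds"` divides the odds of death by `OR^(hours saved)`,
#'   `"risk"` divides the probability directly. The odds scale is the
#'   default; the risk scale is retained as a sensitivity switch.
#' @return A list of class `acute_effect_params`.
#' @export
acute_effect_params <- function(ard_per_minute = 0.0008,
                                mortality_or_per_hour = 1.16,
                                otp_or_override = NULL,
                                mortality_rule = c("odds", "risk")) {
  mortality_rule <- match.arg(mortality_rule)
  ard_per_minute <- check_number(ard_per_minute, "ard_per_minute", 0, Inf)
  mortality_or_per_hour <- check_number(mortality_or_per_hour,
                                        "mortality_or_per_hour", 1, Inf)
  if (!is.null(otp_or_override)) {
    otp_or_override <- check_number(otp_or_override, "otp_or_override", 1, Inf)
  }
  structure(list(ard_per_minute = ard_per_minute,
                 mortality_or_per_hour = mortality_or_per_hour,
                 otp_or_override = otp_or_override,
                 mortality_rule = mortality_rule),
            class = "acute_effect_params")
}

#' Annual recurrent-stroke probability schedule
#'
#' Recurrence risk is highest in the first year after the stroke and declines
#' with time since the event; beyond ten years it is taken as zero.
#'
#' @param p_year1,p_years2_5,p_years6_10,p_beyond10 annual recurrence
#'   probabilities by period since the stroke; non-increasing across periods.
#' @return A list of class `recurrence_schedule`.
#' @export
recurrence_schedule <- function(p_year1 = 0.111, p_years2_5 = 0.041,
                                p_years6_10 = 0.027, p_beyond10 = 0) {
  p <- c(p_year1 = check_number(p_year1, "p_year1", 0, 1, strict_upper = TRUE),
         p_years2_5 = check_number(p_years2_5, "p_years2_5", 0, 1,
                                   strict_upper = TRUE),
         p_years6_10 = check_number(p_years6_10, "p_years6_10", 0, 1,
                                    strict_upper = TRUE),
         p_beyond10 = check_number(p_beyond10, "p_beyond10", 0, 1,
                                   strict_upper = TRUE))
  if (any(diff(p) > 1e-12)) {
    stopf("recurrence probabilities must be non-increasing over periods")
  }
  structure(as.list(p), class = "recurrence_schedule")
}

#' Annual Markov transition parameters
#'
#' @param p_excess_death_mrs02 annual stroke-related excess death probability
#'   from mRS 0-2 (default 0.008).
#' @param p_excess_death_mrs35 annual excess death probability from mRS 3-5
#'   (default 0.039).
#' @param recurrence a [recurrence_schedule()].
#' @param recurrent_exit exit distribution of the one-year recurrent-stroke
#'   tunnel state over (mRS 0-2, mRS 3-5, death); defaults to
#'   (0.250, 0.605, 0.145) and must sum to 1.
#' @return A list of class `transition_params`.
#' @export
transition_params <- function(p_excess_death_mrs02 = 0.008,
                              p_excess_death_mrs35 = 0.039,
                              recurrence = recurrence_schedule(),
                              recurrent_exit = c(p_mrs02 = 0.250,
                                                 p_mrs35 = 0.605,
                                                 p_death = 0.145)) {
  if (!inherits(recurrence, "recurrence_schedule")) {
    recurrence <- do.call(recurrence_schedule, as.list(recurrence))
  }
  ex <- unlist(recurrent_exit)
  if (length(ex) != 3L) stopf("recurrent_exit needs 3 components")
  if (!is.null(names(ex)) && all(c("p_mrs02", "p_mrs35", "p_death") %in% names(ex))) {
    ex <- ex[c("p_mrs02", "p_mrs35", "p_death")]
  }
  names(ex) <- c("p_mrs02", "p_mrs35", "p_death")
  for (i in seq_along(ex)) check_probability(ex[[i]], names(ex)[i])
  if (abs(sum(ex) - 1) > 1e-6) {
    stopf("recurrent_exit must sum to 1; got sum %.10g", sum(ex))
  }
  structure(list(
    p_excess_death_mrs02 = check_probability(p_excess_death_mrs02,
                                             "p_excess_death_mrs02"),
    p_excess_death_mrs35 = check_probability(p_excess_death_mrs35,
                                             "p_excess_death_mrs35"),
    recurrence = recurrence,
    recurrent_exit = ex
  ), class = "transition_params")
}

#' Health-state utility weights
#'
#' Annual utilities in \[0, 1\]. The recurrent-stroke tunnel year defaults to
#' the mRS 3-5 utility (an acute disability year); the general-population
#' pathway used by the primary-prevention target defaults to the mRS 0-2
#' utility. Both are configurable.
#'
#' @param u_mrs02,u_mrs35,u_dead utilities per year for the live mRS bands
#'   and death (`u_dead` must be 0).
#' @param u_recurrent_year utility during the recurrent-stroke year; defaults
#'   to `u_mrs35`.
#' @param u_general_population utility of the general-population pathway;
#'   defaults to `u_mrs02`.
#' @return A list of class `utility_set`.
#' @export
utility_set <- function(u_mrs02 = 0.71, u_mrs35 = 0.20, u_dead = 0,
                        u_recurrent_year = NULL,
                        u_general_population = NULL) {
  u_dead <- check_probability(u_dead, "u_dead")
  if (u_dead != 0) stopf("u_dead must be 0 (got %g)", u_dead)
  structure(list(
    u_mrs02 = check_probability(u_mrs02, "u_mrs02"),
    u_mrs35 = check_probability(u_mrs35, "u_mrs35"),
    u_dead = u_dead,
    u_recurrent_year = check_probability(u_recurrent_year %||% u_mrs35,
                                         "u_recurrent_year"),
    u_general_population = check_probability(u_general_population %||% u_mrs02,
                                             "u_general_population")
  ), class = "utility_set")
}

#' Cost parameters
#'
#' All amounts are euros of the stated `currency_year` (2023 by default).
#' Acute (first 90 days) costs are keyed by treatment arm and mRS band;
#' long-term costs are annual per mRS band, with a one-off cost on entering
#' the recurrent-stroke state.
#'
#' @param acute_cost_by_arm_and_band numeric matrix with rows
#'   `standard`, `ivt`, `evt` and columns `mrs02`, `mrs35`, `mrs6`: euros per
#'   patient for the first 90 days.
#' @param annual_cost_mrs02,annual_cost_mrs35 annual long-term care costs.
#' @param recurrent_event_cost one-off cost charged on entry to the
#'   recurrent-stroke state (covers the recurrent acute episode year).
#' @param currency_year calendar year tag of the cost basis.
#' @return A list of class `cost_set`.
#' @export
cost_set <- function(acute_cost_by_arm_and_band,
                     annual_cost_mrs02, annual_cost_mrs35,
                     recurrent_event_cost, currency_year = 2023) {
  m <- as.matrix(acute_cost_by_arm_and_band)
  if (!all(TREATMENT_ARMS %in% rownames(m)) ||
      !all(c("mrs02", "mrs35", "mrs6") %in% colnames(m))) {
    stopf(paste0("acute_cost_by_arm_and_band needs rows ",
                 "{standard, ivt, evt} and columns {mrs02, mrs35, mrs6}"))
  }
  m <- m[TREATMENT_ARMS, c("mrs02", "mrs35", "mrs6"), drop = FALSE]
  if (any(!is.finite(m)) || any(m < 0)) stopf("acute costs must be >= 0")
  structure(list(
    acute_cost_by_arm_and_band = m,
    annual_cost_mrs02 = check_number(annual_cost_mrs02, "annual_cost_mrs02", 0),
    annual_cost_mrs35 = check_number(annual_cost_mrs35, "annual_cost_mrs35", 0),
    recurrent_event_cost = check_number(recurrent_event_cost,
                                        "recurrent_event_cost", 0),
    currency_year = check_number(currency_year, "currency_year", 1900, 2100)
  ), class = "cost_set")
}

#' All-cause mortality life table
#'
#' @param age integer ages, consecutive from the first age listed.
#' @param qx annual probability of death at each age, in \[0, 1\]; the final
#'   age (`max_age`) must have `qx = 1` so the cohort is fully absorbed.
#' @return A list of class `life_table` with fields `age`, `qx`, `max_age`.
#' @export
life_table <- function(age, qx) {
  age <- as.integer(age)
  qx <- as.numeric(qx)
  if (length(age) != length(qx) || length(age) < 2L) {
    stopf("life table needs matching age and qx vectors of length >= 2")
  }
  if (any(diff(age) != 1L)) stopf("life-table ages must be consecutive integers")
  if (any(qx < 0 | qx > 1 | !is.finite(qx))) stopf("qx values must lie in [0, 1]")
  if (qx[length(qx)] != 1) {
    stopf("qx at max_age must equal 1 (got %g at age %d)",
          qx[length(qx)], age[length(age)])
  }
  structure(list(age = age, qx = qx, max_age = age[length(age)]),
            class = "life_table")
}

#' Annual death probability at a given age
#'
#' Ages beyond the table are treated as certain death; ages below the first
#' tabulated age take the first tabulated value.
#'
#' @param lt a [life_table()].
#' @param age age in years (fractional ages are floored).
#' @return Annual probability of death.
#' @export
qx_at <- function(lt, age) {
  age <- floor(age)
  ifelse(age > lt$max_age, 1,
         lt$qx[pmax(1L, pmin(length(lt$qx), age - lt$age[1L] + 1L))])
}

#' Full country parameterisation
#'
#' Bundles everything the two-stage model needs for one country.
#'
#' @param name country label.
#' @param cohort_start_age age of the incident cohort at the index stroke.
#' @param discount_rate annual discount rate in \[0, 0.1\].
#' @param annual_incidence incident AIS patients per year (population scaling).
#' @param profile a [treatment_profile()].
#' @param outcomes an [outcome_table()].
#' @param transitions a [transition_params()].
#' @param utilities a [utility_set()].
#' @param costs a [cost_set()].
#' @param life_table a [life_table()].
#' @param acute_effects an [acute_effect_params()].
#' @param synthetic_fields character vector naming inputs that are synthetic
#'   stand-ins rather than sourced national data (metadata only).
#' @return A list of class `country_config`.
#' @export
country_config <- function(name, cohort_start_age, discount_rate,
                           annual_incidence, profile, outcomes, transitions,
                           utilities, costs, life_table, acute_effects,
                           synthetic_fields = character()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stopf("country name must be a non-empty string")
  }
  for (cls in list(c("profile", "treatment_profile"),
                   c("outcomes", "outcome_table"),
                   c("transitions", "transition_params"),
                   c("utilities", "utility_set"),
                   c("costs", "cost_set"),
                   c("life_table", "life_table"),
                   c("acute_effects", "acute_effect_params"))) {
    obj <- get(cls[1L])
    if (!inherits(obj, cls[2L])) {
      stopf("'%s' must be a %s object", cls[1L], cls[2L])
    }
  }
  cohort_start_age <- check_number(cohort_start_age, "cohort_start_age", 18, 100)
  if (cohort_start_age >= life_table$max_age) {
    stopf("cohort_start_age (%g) must be below the life-table max_age (%d)",
          cohort_start_age, life_table$max_age)
  }
  structure(list(
    name = name,
    cohort_start_age = cohort_start_age,
    discount_rate = check_number(discount_rate, "discount_rate", 0, 0.1),
    annual_incidence = check_number(annual_incidence, "annual_incidence", 0),
    profile = profile,
    outcomes = outcomes,
    transitions = transitions,
    utilities = utilities,
    costs = costs,
    life_table = life_table,
    acute_effects = acute_effects,
    synthetic_fields = as.character(synthetic_fields)
  ), class = "country_config")
}

#' Re-validate a country configuration
#'
#' Rebuilds the object through every typed constructor, so all component
#' invariants are re-checked. Useful after programmatic edits.
#'
#' @param config a `country_config` (possibly hand-edited).
#' @return The validated config, invisibly.
#' @export
validate_country_config <- function(config) {
  out <- country_config(
    name = config$name,
    cohort_start_age = config$cohort_start_age,
    discount_rate = config$discount_rate,
    annual_incidence = config$annual_incidence,
    profile = do.call(treatment_profile, unclass(config$profile)),
    outcomes = outcome_table(config$outcomes$standard, config$outcomes$ivt,
                             config$outcomes$evt),
    transitions = transition_params(
      config$transitions$p_excess_death_mrs02,
      config$transitions$p_excess_death_mrs35,
      config$transitions$recurrence,
      config$transitions$recurrent_exit),
    utilities = do.call(utility_set, unclass(config$utilities)),
    costs = do.call(cost_set, unclass(config$costs)),
    life_table = life_table(config$life_table$age, config$life_table$qx),
    acute_effects = do.call(acute_effect_params,
                            unclass(config$acute_effects)),
    synthetic_fields = config$synthetic_fields %||% character()
  )
  invisible(out)
}

#' @export
print.country_config <- function(x, ...) {
  cat(sprintf("<country_config: %s>\n", x$name))
  cat(sprintf("  cohort: start age %g, discount %.3f, incidence %g/yr\n",
              x$cohort_start_age, x$discount_rate, x$annual_incidence))
  cat(sprintf("  profile: IVT %.1f%% (OTN %g min), EVT %.1f%% (OTP %g min)\n",
              100 * x$profile$ivt_rate, x$profile$otn_minutes,
              100 * x$profile$evt_rate, x$profile$otp_minutes))
  if (length(x$synthetic_fields)) {
    cat("  synthetic inputs:", paste(x$synthetic_fields, collapse = ", "), "\n")
  }
  invisible(x)
}
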