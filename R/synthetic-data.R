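# Synthetic country inputs. The shared clinical parameters (90-day outcome
# table, transition probabilities, utilities, acute-effect parameters) and
# the seven countries' treatment profiles are published values; the
# remaining national inputs (mRS-band costs, life tables, cohort start age,
# annual incidence) are synthetic stand-ins generated here, flagged in each
# config's `synthetic_fields`. Discount rates follow the national HTA
# guideline conventions.

#' Parameters of the synthetic input generator
#'
#' @param seed integer seed; the generator is a pure function of it.
#' @param cost_scale multiplicative euro scale applied to all generated
#'   costs (captures between-country price-level differences).
#' @param gompertz_a,gompertz_b Gompertz baseline hazard and ageing rate of
#'   the synthetic life table (`hazard = makeham + a * exp(b * age)`).
#' @param makeham age-independent hazard component.
#' @param discount_rate_range interval the discount rate is drawn from.
#' @param start_age_range interval the cohort start age is drawn from.
#' @param max_age life-table closure age (`qx = 1` there).
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(seed, cost_scale = 1,
                             gompertz_a = 2e-5, gompertz_b = 0.10,
                             makeham = 5e-4,
                             discount_rate_range = c(0.015, 0.04),
                             start_age_range = c(60, 80),
                             max_age = 100) {
  check_number(seed, "seed")
  structure(list(
    seed = as.integer(seed),
    cost_scale = check_number(cost_scale, "cost_scale", 0, Inf,
                              strict_lower = TRUE),
    gompertz_a = check_number(gompertz_a, "gompertz_a", 0, Inf,
                              strict_lower = TRUE),
    gompertz_b = check_number(gompertz_b, "gompertz_b", 0, Inf,
                              strict_lower = TRUE),
    makeham = check_number(makeham, "makeham", 0),
    discount_rate_range = sort(c(
      check_number(discount_rate_range[1], "discount_rate_range[1]", 0, 0.1),
      check_number(discount_rate_range[2], "discount_rate_range[2]", 0, 0.1))),
    start_age_range = sort(c(
      check_number(start_age_range[1], "start_age_range[1]", 18, 95),
      check_number(start_age_range[2], "start_age_range[2]", 18, 95))),
    max_age = as.integer(check_number(max_age, "max_age", 60, 110))
  ), class = "generator_params")
}

#' Generate a synthetic all-cause mortality life table
#'
#' Gompertz-Makeham annual death probabilities rising with age,
#' `qx = 1 - exp(-(makeham + a exp(b age)))`, with small seeded jitter on
#' the hazard parameters and `qx = 1` at the closure age. Probabilities
#' reaching 1 before the closure age are clamped with a warning.
#'
#' @param params a [generator_params()].
#' @return A [life_table()] over ages 0 to `max_age`.
#' @export
generate_life_table <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  with_seed(params$seed + 1L, {
    a <- params$gompertz_a * exp(rnorm(1, 0, 0.15))
    b <- params$gompertz_b + rnorm(1, 0, 0.004)
    ages <- 0:params$max_age
    hazard <- params$makeham + a * exp(b * ages)
    qx <- 1 - exp(-hazard)
    if (any(qx[-length(qx)] >= 1)) {
      warnf("life-table hazard reaches certain death before the closure age; clamping")
      qx <- pmin(qx, 1)
    }
    qx[length(qx)] <- 1
    life_table(ages, qx)
  })
}

#' Period life expectancy from a life table
#'
#' Curtate expectation of remaining life at `age`: the sum over future years
#' of the cumulative survival probability.
#'
#' @param lt a [life_table()].
#' @param age age in years.
#' @return Expected remaining whole life-years.
#' @export
life_expectancy <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  age <- floor(check_number(age, "age", 0, lt$max_age))
  horizon <- lt$max_age - age + 1
  surv <- cumprod(1 - qx_at(lt, age + seq_len(horizon) - 1))
  sum(surv)
}

#' Collapse six mRS-category costs into the model's two live bands
#'
#' Weighted averages of the per-category costs: categories 1-3 (mRS 0-2)
#' and 4-6 (mRS 3-5), each with its own weight simplex.
#'
#' @param category_costs numeric vector of 6 per-category costs (mRS 0-5).
#' @param weights list with `mrs02` and `mrs35`, each a 3-element weight
#'   simplex.
#' @return Named numeric vector with `mrs02` and `mrs35` band costs.
#' @export
collapse_mrs_costs <- function(category_costs,
                               weights = list(mrs02 = rep(1, 3) / 3,
                                              mrs35 = rep(1, 3) / 3)) {
  if (length(category_costs) != 6L || any(category_costs < 0)) {
    stopf("category_costs must be 6 non-negative values (mRS 0 through 5)")
  }
  for (band in c("mrs02", "mrs35")) {
    w <- weights[[band]]
    if (is.null(w) || length(w) != 3L || any(w < 0) ||
        abs(sum(w) - 1) > 1e-9) {
      stopf("weights$%s must be a 3-element simplex", band)
    }
  }
  c(mrs02 = sum(category_costs[1:3] * weights$mrs02),
    mrs35 = sum(category_costs[4:6] * weights$mrs35))
}

#' Generate a synthetic cost set
#'
#' Draws six per-mRS-category annual cost levels (monotone increasing in
#' mRS severity), collapses them to the model's two live bands by the given
#' weights, and builds arm-specific acute 90-day costs ordered
#' EVT > IVT > standard care.
#'
#' @param params a [generator_params()].
#' @param mrs_band_weights per-band collapse weight simplexes, as in
#'   [collapse_mrs_costs()].
#' @return A [cost_set()].
#' @export
generate_cost_set <- function(params,
                              mrs_band_weights = list(mrs02 = rep(1, 3) / 3,
                                                      mrs35 = rep(1, 3) / 3)) {
  stopifnot(inherits(params, "generator_params"))
  with_seed(params$seed + 2L, {
    base_levels <- c(1500, 3200, 6500, 14000, 22000, 31000)
    cats <- sort(base_levels * params$cost_scale * exp(rnorm(6, 0, 0.12)))
    bands <- collapse_mrs_costs(cats, mrs_band_weights)

    acute_band <- c(mrs02 = 4200, mrs35 = 8200, mrs6 = 5200) *
      params$cost_scale * exp(rnorm(3, 0, 0.10))
    ivt_addon <- 1400 * params$cost_scale * exp(rnorm(1, 0, 0.10))
    evt_addon <- ivt_addon + 8000 * params$cost_scale * exp(rnorm(1, 0, 0.10))
    acute <- rbind(standard = acute_band,
                   ivt = acute_band + ivt_addon,
                   evt = acute_band + evt_addon)
    colnames(acute) <- c("mrs02", "mrs35", "mrs6")

    cost_set(acute_cost_by_arm_and_band = acute,
             annual_cost_mrs02 = bands[["mrs02"]],
             annual_cost_mrs35 = bands[["mrs35"]],
             recurrent_event_cost = acute["standard", "mrs35"] *
               exp(rnorm(1, 0, 0.10)),
             currency_year = 2023)
  })
}

# Shared published clinical parameters (identical across countries).
base_outcome_table <- function() {
  outcome_table(standard = mrs_distribution(0.22, 0.55, 0.23),
                ivt = mrs_distribution(0.27, 0.54, 0.19),
                evt = mrs_distribution(0.46, 0.40, 0.14))
}

base_transition_params <- function() transition_params()

base_utility_set <- function() utility_set()

#' Generate a complete synthetic country configuration
#'
#' Random but valid national inputs: a treatment profile spanning met and
#' unmet targets, synthetic costs and life table, and the shared published
#' clinical parameters. Pure function of the seed.
#'
#' @param params a [generator_params()].
#' @param name config label; defaults to `"synthetic-<seed>"`.
#' @return A [country_config()].
#' @export
generate_country_config <- function(params,
                                    name = sprintf("synthetic-%d",
                                                   params$seed)) {
  stopifnot(inherits(params, "generator_params"))
  lt <- generate_life_table(params)
  costs <- generate_cost_set(params)
  with_seed(params$seed + 3L, {
    profile <- treatment_profile(
      ivt_rate = runif(1, 0.05, 0.21),
      evt_rate = runif(1, 0.005, 0.06),
      otn_minutes = round(runif(1, 60, 240)),
      otp_minutes = round(runif(1, 130, 420)))
    discount <- runif(1, params$discount_rate_range[1],
                      params$discount_rate_range[2])
    start_age <- round(runif(1, params$start_age_range[1],
                             params$start_age_range[2]))
    incidence <- round(runif(1, 2e4, 2e5))
    country_config(
      name = name,
      cohort_start_age = start_age,
      discount_rate = discount,
      annual_incidence = incidence,
      profile = profile,
      outcomes = base_outcome_table(),
      transitions = base_transition_params(),
      utilities = base_utility_set(),
      costs = costs,
      life_table = lt,
      acute_effects = acute_effect_params(),
      synthetic_fields = c("costs", "life_table", "discount_rate",
                           "cohort_start_age", "annual_incidence",
                           "profile"))
  })
}

#' The seven preconfigured European countries
#'
#' Treatment profiles (onset-to-needle and onset-to-puncture times, IVT and
#' EVT rates) are the published baseline national performance values; the
#' outcome table, transition probabilities, utilities and acute-effect
#' parameters are the shared published clinical inputs (the United Kingdom
#' carries a mortality OR override of 1 for onset-to-puncture effects).
#' Costs, life tables, cohort start ages and annual incidences are synthetic
#' stand-ins, generated deterministically from `base_seed` and flagged in
#' `synthetic_fields`; discount rates follow national HTA guideline
#' conventions.
#'
#' @param base_seed seed anchoring all synthetic components.
#' @return Named list of seven [country_config()] objects.
#' @export
fixture_countries <- function(base_seed = 20230L) {
  tab <- data.frame(
    name = c("France", "Germany", "Italy", "Netherlands", "Spain",
             "Sweden", "United Kingdom"),
    otn = c(153, 96, 160, 85, 57, 84, 100),
    otp = c(244, 160, 225, 180, 166, 127, 378),
    ivt = c(9.2, 17.5, 7.4, 20.6, 7.5, 15, 11.7) / 100,
    evt = c(5.3, 5.2, 1.7, 4.6, 3.6, 2.2, 0.5) / 100,
    discount = c(0.025, 0.03, 0.03, 0.03, 0.03, 0.03, 0.035),
    cost_scale = c(1.05, 1.10, 0.95, 1.10, 0.90, 1.15, 1.00),
    incidence = c(110000, 200000, 120000, 30000, 85000, 25000, 100000),
    stringsAsFactors = FALSE)

  configs <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    gp <- generator_params(seed = base_seed + i,
                           cost_scale = row$cost_scale)
    effects <- if (row$name == "United Kingdom") {
      acute_effect_params(otp_or_override = 1)
    } else {
      acute_effect_params()
    }
    country_config(
      name = row$name,
      cohort_start_age = 70,
      discount_rate = row$discount,
      annual_incidence = row$incidence,
      profile = treatment_profile(row$ivt, row$evt, row$otn, row$otp),
      outcomes = base_outcome_table(),
      transitions = base_transition_params(),
      utilities = base_utility_set(),
      costs = generate_cost_set(gp),
      life_table = generate_life_table(gp),
      acute_effects = effects,
      synthetic_fields = c("costs", "life_table", "cohort_start_age",
                           "annual_incidence"))
  })
  names(configs) <- tab$name
  configs
}
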