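# Shared fixtures, built in code.

# Published shared clinical inputs.
base_outcomes <- function() {
  outcome_table(standard = mrs_distribution(0.22, 0.55, 0.23),
                ivt = mrs_distribution(0.27, 0.54, 0.19),
                evt = mrs_distribution(0.46, 0.40, 0.14))
}

flat_life_table <- function(qx = 0, max_age = 100) {
  life_table(0:max_age, c(rep(qx, max_age), 1))
}

simple_costs <- function(annual02 = 2000, annual35 = 8000, recurrent = 9000,
                         acute_base = 5000) {
  m <- matrix(acute_base, 3, 3,
              dimnames = list(c("standard", "ivt", "evt"),
                              c("mrs02", "mrs35", "mrs6")))
  m["ivt", ] <- m["ivt", ] + 1500
  m["evt", ] <- m["evt", ] + 9000
  cost_set(m, annual02, annual35, recurrent)
}

# Small deterministic config for unit tests; defaults give a short horizon.
toy_config <- function(name = "Toyland", start_age = 70, max_age = 100,
                       qx = 0, discount = 0.03,
                       ivt = 0.10, evt = 0.03, otn = 150, otp = 250,
                       transitions = transition_params(),
                       utilities = utility_set(),
                       costs = simple_costs(),
                       effects = acute_effect_params(),
                       incidence = 50000) {
  country_config(
    name = name, cohort_start_age = start_age, discount_rate = discount,
    annual_incidence = incidence,
    profile = treatment_profile(ivt, evt, otn, otp),
    outcomes = base_outcomes(),
    transitions = transitions,
    utilities = utilities,
    costs = costs,
    life_table = flat_life_table(qx, max_age),
    acute_effects = effects)
}

expect_simplex <- function(d, tol = 1e-9) {
  expect_true(all(unclass(d) >= -tol))
  expect_equal(sum(unclass(d)), 1, tolerance = tol)
}
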