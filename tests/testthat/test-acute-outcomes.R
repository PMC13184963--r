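# 90-day decision tree: arm mixing, rate shifts and time-to-treatment
# effects.

test_that("cohort mixing is the convex combination of arm outcomes", {
  tab <- base_outcomes()
  expect_equal(unclass(mix_90day_distribution(arm_mix(1, 0, 0), tab)),
               c(p_mrs02 = 0.22, p_mrs35 = 0.55, p_mrs6 = 0.23))
  expect_equal(unclass(mix_90day_distribution(arm_mix(0, 0, 1), tab)),
               c(p_mrs02 = 0.46, p_mrs35 = 0.40, p_mrs6 = 0.14))
  d <- mix_90day_distribution(arm_mix(0.773, 0.175, 0.052), tab)
  expect_equal(d[["p_mrs02"]], 0.773 * 0.22 + 0.175 * 0.27 + 0.052 * 0.46)
  expect_equal(d[["p_mrs02"]], 0.24123, tolerance = 1e-12)
})

test_that("mixing is linear in the mix and preserves the simplex (property)", {
  tab <- base_outcomes()
  set.seed(42)
  for (i in 1:25) {
    w <- as.numeric(stats::rmultinom(1, 1000, c(1, 1, 1))) / 1000
    m1 <- arm_mix(w[1], w[2], w[3])
    d1 <- mix_90day_distribution(m1, tab)
    expect_simplex(d1)
    # linearity: mixture of mixes equals mix of mixtures
    m2 <- arm_mix(1, 0, 0)
    lam <- runif(1)
    blend <- arm_mix(lam * w[1] + (1 - lam) * 1, lam * w[2], lam * w[3])
    d2 <- mix_90day_distribution(m2, tab)
    db <- mix_90day_distribution(blend, tab)
    expect_equal(unclass(db), lam * unclass(d1) + (1 - lam) * unclass(d2),
                 tolerance = 1e-12)
  }
})

test_that("rate shifts pull the increment from standard care only", {
  fr <- treatment_profile(0.092, 0.053, 153, 244)
  shifted <- apply_rate_shift(fr, "ivt", 0.15)
  expect_equal(shifted$ivt_rate, 0.15)
  expect_equal(shifted$evt_rate, 0.053)
  expect_equal(standard_care_share(fr) - standard_care_share(shifted),
               0.15 - 0.092)
  # cohort-level mRS 0-2 change: share moved times arm outcome difference
  tab <- base_outcomes()
  d0 <- mix_90day_distribution(arm_mix_from_profile(fr), tab)
  d1 <- mix_90day_distribution(arm_mix_from_profile(shifted), tab)
  expect_equal(d1[["p_mrs02"]] - d0[["p_mrs02"]], 0.058 * (0.27 - 0.22),
               tolerance = 1e-12)

  # identity when the target equals the current rate
  expect_equal(apply_rate_shift(fr, "evt", 0.053), fr)
  # already-met targets signal a typed condition
  expect_error(apply_rate_shift(fr, "ivt", 0.05),
               class = "strokecea_target_met")
  # infeasible increment
  tight <- treatment_profile(0.5, 0.45, 100, 200)
  expect_error(apply_rate_shift(tight, "ivt", 0.7), "standard-care share")
})

test_that("rate shifts conserve total cohort share exactly", {
  set.seed(7)
  for (i in 1:20) {
    p <- treatment_profile(runif(1, 0, 0.12), runif(1, 0, 0.04),
                           120, 240)
    s <- apply_rate_shift(p, sample(c("ivt", "evt"), 1), 0.15)
    expect_equal(standard_care_share(s) + s$ivt_rate + s$evt_rate, 1,
                 tolerance = 1e-15)
  }
})

test_that("minutes_saved honours the strict threshold by aiming 1 minute under", {
  expect_equal(minutes_saved(153, 120), 34)
  expect_equal(minutes_saved(96, 120), 0)
  expect_equal(minutes_saved(378, 200), 179)
  expect_equal(minutes_saved(119, 120), 0)
  expect_equal(minutes_saved(120, 120), 1)
})

test_that("time effect moves mRS 0-2 linearly and mortality on the odds scale", {
  evt <- mrs_distribution(0.46, 0.40, 0.14)
  fx <- acute_effect_params()

  # hand-derived: odds 0.14/0.86 divided by 1.16^(45/60), back-transformed
  d <- apply_time_effect(evt, 45, fx)
  odds_new <- (0.14 / 0.86) / 1.16^0.75
  expect_equal(d[["p_mrs6"]], odds_new / (1 + odds_new), tolerance = 1e-12)
  expect_equal(d[["p_mrs02"]], 0.46 + 45 * 0.0008)
  expect_equal(round(unclass(d), 5),
               c(p_mrs02 = 0.496, p_mrs35 = 0.37687, p_mrs6 = 0.12713))

  # zero minutes saved is the identity
  expect_equal(unclass(apply_time_effect(evt, 0, fx)), unclass(evt))
  # ard = 0 and OR = 1 is the identity at any saving
  null_fx <- acute_effect_params(ard_per_minute = 0, mortality_or_per_hour = 1)
  expect_equal(unclass(apply_time_effect(evt, 300, null_fx)), unclass(evt))

  # OR override 1: whole gain drawn from mRS 3-5 (equal and opposite)
  uk <- acute_effect_params(otp_or_override = 1)
  d2 <- apply_time_effect(evt, 179, uk, use_otp_override = TRUE)
  expect_equal(unclass(d2), c(p_mrs02 = 0.6032, p_mrs35 = 0.2568,
                              p_mrs6 = 0.14))

  # risk-scale switch divides the probability directly
  rk <- acute_effect_params(mortality_rule = "risk")
  d3 <- apply_time_effect(evt, 60, rk)
  expect_equal(d3[["p_mrs6"]], 0.14 / 1.16)

  # infeasible effect errors
  expect_error(apply_time_effect(evt, 1000, uk, use_otp_override = TRUE),
               "feasible range")
})

test_that("p_mrs02 rises and p_mrs6 falls monotonically in minutes saved (property)", {
  evt <- mrs_distribution(0.46, 0.40, 0.14)
  fx <- acute_effect_params()
  saved <- seq(0, 180, by = 15)
  p02 <- vapply(saved, function(s) apply_time_effect(evt, s, fx)[["p_mrs02"]],
                numeric(1))
  p6 <- vapply(saved, function(s) apply_time_effect(evt, s, fx)[["p_mrs6"]],
               numeric(1))
  expect_true(all(diff(p02) > 0))
  expect_true(all(diff(p6) < 0))
  for (s in saved) expect_simplex(apply_time_effect(evt, s, fx))
})

test_that("cohort-level time-target gain is arm share times arm-level gain", {
  # bilinearity, checked against brute-force enumeration of a 1000-patient
  # cohort assigned to arms in exact proportions
  tab <- base_outcomes()
  profile <- treatment_profile(0.2, 0.05, 150, 250)
  fx <- acute_effect_params(otp_or_override = 1)
  saved <- 50
  shifted_evt <- apply_time_effect(tab$evt, saved, fx, use_otp_override = TRUE)

  mix <- arm_mix_from_profile(profile)
  d0 <- mix_90day_distribution(mix, tab)
  d1 <- mix_90day_distribution(mix, outcome_table(tab$standard, tab$ivt,
                                                  shifted_evt))
  cohort_gain <- d1[["p_mrs02"]] - d0[["p_mrs02"]]
  arm_gain <- shifted_evt[["p_mrs02"]] - tab$evt[["p_mrs02"]]
  expect_equal(cohort_gain, 0.05 * arm_gain, tolerance = 1e-12)

  n <- 1000
  counts <- round(n * unclass(mix))
  per_patient_before <- (counts[["standard"]] * tab$standard[["p_mrs02"]] +
                           counts[["ivt"]] * tab$ivt[["p_mrs02"]] +
                           counts[["evt"]] * tab$evt[["p_mrs02"]]) / n
  per_patient_after <- (counts[["standard"]] * tab$standard[["p_mrs02"]] +
                          counts[["ivt"]] * tab$ivt[["p_mrs02"]] +
                          counts[["evt"]] * shifted_evt[["p_mrs02"]]) / n
  expect_equal(per_patient_after - per_patient_before, cohort_gain,
               tolerance = 1e-12)
})
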