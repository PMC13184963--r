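# Lifetime Markov cohort model: transition rows, cohort projection, reward
# accumulation, and the microsimulation oracle.

test_that("transition rows encode recurrence schedule, excess and background death", {
  tp <- transition_params()
  lt0 <- flat_life_table(0)

  expect_equal(transition_row("mrs02", 1, 70, tp, lt0),
               c(mrs02 = 0.881, mrs35 = 0, recurrent = 0.111, dead = 0.008))
  expect_equal(transition_row("mrs02", 12, 70, tp, lt0),
               c(mrs02 = 0.992, mrs35 = 0, recurrent = 0, dead = 0.008))

  # independent competing risks: 1 - (1-a)(1-qx)
  lt5 <- flat_life_table(0.05)
  row <- transition_row("mrs35", 3, 70, tp, lt5)
  expect_equal(row[["dead"]], 1 - (1 - 0.039) * (1 - 0.05))
  expect_equal(row[["recurrent"]], 0.041)
  expect_equal(row[["mrs35"]], 0.87195)
  expect_equal(sum(row), 1)

  # recurrent tunnel exit with background mortality folded into death
  ex <- transition_row("recurrent", 1, 70, tp, lt0)
  expect_equal(ex, c(mrs02 = 0.250, mrs35 = 0.605, recurrent = 0,
                     dead = 0.145))
  ex5 <- transition_row("recurrent", 1, 70, tp, lt5)
  expect_equal(ex5[["dead"]], 1 - (1 - 0.145) * (1 - 0.05))
  expect_equal(ex5[["mrs02"]] / ex5[["mrs35"]], 0.250 / 0.605)
  expect_equal(sum(ex5), 1)

  # infeasible rows are an error, not a silent renormalisation
  lt_hi <- flat_life_table(0.95)
  expect_error(transition_row("mrs02", 1, 70, tp, lt_hi), "infeasible")
  # at the closure age the row is certain death
  expect_equal(transition_row("mrs02", 1, 101, tp, lt0)[["dead"]], 1)
})

test_that("cohort projection conserves occupancy and reproduces the one-step case", {
  # absorbing-free identity: no recurrence, no excess death, no background death
  quiet <- transition_params(p_excess_death_mrs02 = 0,
                             p_excess_death_mrs35 = 0,
                             recurrence = recurrence_schedule(0, 0, 0, 0))
  cfg <- toy_config(transitions = quiet, qx = 0)
  tr <- run_cohort(mrs_distribution(0.6, 0.3, 0.1), cfg, horizon = 10)
  expect_true(all(abs(tr$occ_mrs02 - 0.6) < 1e-12))
  expect_true(all(abs(tr$occ_mrs35 - 0.3) < 1e-12))
  expect_true(all(abs(tr$occ_dead - 0.1) < 1e-12))

  # hand-computed single step with the baseline parameters
  cfg2 <- toy_config(qx = 0)
  tr2 <- run_cohort(mrs_distribution(0.6, 0.3, 0.1), cfg2, horizon = 2)
  expect_equal(as.numeric(tr2[2, c("occ_mrs02", "occ_mrs35", "occ_recurrent",
                                   "occ_dead")]),
               c(0.5286, 0.2550, 0.0999, 0.1165), tolerance = 1e-12)
  expect_equal(sum(tr2[2, c("occ_mrs02", "occ_mrs35", "occ_recurrent",
                            "occ_dead")]), 1)

  # the tunnel is strict: occupants are fully redistributed next cycle in
  # the exit proportions (here qx = 0 so exactly 0.250/0.605/0.145)
  tr3 <- run_cohort(mrs_distribution(0.6, 0.3, 0.1), cfg2, horizon = 3)
  rec_t2 <- tr3$occ_recurrent[2]
  stay_year2 <- 1 - 0.041 - 0.008 # mrs02 stay probability in year 2
  d02 <- tr3$occ_mrs02[3] - tr3$occ_mrs02[2] * stay_year2
  expect_equal(d02, rec_t2 * 0.250, tolerance = 1e-12)
  expect_equal(tr3$occ_recurrent[3],
               tr3$occ_mrs02[2] * 0.041 + tr3$occ_mrs35[2] * 0.041,
               tolerance = 1e-12)
})

test_that("occupancy sums to 1 and death is monotone on every run (property)", {
  for (s in c(3L, 14L, 27L)) {
    cfg <- generate_country_config(generator_params(s))
    d90 <- mix_90day_distribution(arm_mix_from_profile(cfg$profile),
                                  cfg$outcomes)
    for (reset in c(FALSE, TRUE)) {
      tr <- run_cohort(d90, cfg, reset_clock = reset)
      sums <- tr$occ_mrs02 + tr$occ_mrs35 + tr$occ_recurrent + tr$occ_dead
      expect_true(all(abs(sums - 1) < 1e-9))
      expect_true(all(diff(tr$occ_dead) >= -1e-12))
      expect_equal(tr$occ_dead[nrow(tr)], 1, tolerance = 1e-9)
    }
  }
})

test_that("reward accumulation discounts end-of-cycle and matches hand sums", {
  cfg <- toy_config(transitions = transition_params(
    p_excess_death_mrs02 = 0, p_excess_death_mrs35 = 0,
    recurrence = recurrence_schedule(0, 0, 0, 0)), qx = 0)
  tr <- run_cohort(mrs_distribution(1, 0, 0), cfg, horizon = 2)

  res0 <- accumulate_outcomes(tr, cfg$utilities, cfg$costs, 0)
  expect_equal(res0$total_qalys, 1.42)
  expect_equal(res0$total_qalys, res0$undiscounted$total_qalys)
  expect_equal(res0$total_cost, res0$undiscounted$total_cost)

  res3 <- accumulate_outcomes(tr, cfg$utilities, cfg$costs, 0.03)
  expect_equal(res3$total_qalys, 0.71 / 1.03 + 0.71 / 1.03^2,
               tolerance = 1e-12)
  expect_equal(res3$life_years, 1 / 1.03 + 1 / 1.03^2, tolerance = 1e-12)
  expect_lt(res3$total_qalys, res3$undiscounted$total_qalys)

  # all-dead trace accrues nothing
  trd <- run_cohort(mrs_distribution(0, 0, 1), cfg, horizon = 5)
  resd <- accumulate_outcomes(trd, cfg$utilities, cfg$costs, 0.03)
  expect_equal(resd$total_qalys, 0)
  expect_equal(resd$total_cost, 0)
  expect_equal(resd$life_years, 0)
})

test_that("recurrent entries are charged the event cost once", {
  cfg <- toy_config(qx = 0)
  tr <- run_cohort(mrs_distribution(1, 0, 0), cfg, horizon = 2)
  res <- accumulate_outcomes(tr, cfg$utilities, cfg$costs, 0)
  # cycle 1: all in mrs02; cycle 2: 0.881 stay, 0.111 tunnel, 0.008 dead
  expected_cost <- cfg$costs$annual_cost_mrs02 * (1 + 0.881) +
    0.111 * cfg$costs$recurrent_event_cost
  expect_equal(res$total_cost, expected_cost, tolerance = 1e-12)
})

test_that("raising utilities raises QALYs; raising qx lowers life-years (monotonicity)", {
  cfg <- toy_config(qx = 0.02)
  d90 <- mrs_distribution(0.5, 0.3, 0.2)
  tr <- run_cohort(d90, cfg)
  base <- accumulate_outcomes(tr, cfg$utilities, cfg$costs, 0.03)
  up <- accumulate_outcomes(tr, utility_set(u_mrs02 = 0.8, u_mrs35 = 0.3),
                            cfg$costs, 0.03)
  expect_gt(up$total_qalys, base$total_qalys)

  cfg_hi <- toy_config(qx = 0.06)
  tr_hi <- run_cohort(d90, cfg_hi)
  hi <- accumulate_outcomes(tr_hi, cfg_hi$utilities, cfg_hi$costs, 0.03)
  expect_lt(hi$life_years, base$life_years)
})

test_that("a 10% recurrence cut weakly raises QALYs and strictly cuts recurrent person-years", {
  cfg <- generate_country_config(generator_params(5))
  d90 <- mix_90day_distribution(arm_mix_from_profile(cfg$profile),
                                cfg$outcomes)
  tr0 <- run_cohort(d90, cfg)
  r0 <- accumulate_outcomes(tr0, cfg$utilities, cfg$costs, cfg$discount_rate)

  cut <- config_set(config_set(config_set(cfg,
    "transitions.recurrence.p_year1", 0.111 * 0.9),
    "transitions.recurrence.p_years2_5", 0.041 * 0.9),
    "transitions.recurrence.p_years6_10", 0.027 * 0.9)
  tr1 <- run_cohort(d90, cut)
  r1 <- accumulate_outcomes(tr1, cut$utilities, cut$costs, cut$discount_rate)

  expect_gte(r1$total_qalys, r0$total_qalys)
  expect_lt(sum(tr1$occ_recurrent), sum(tr0$occ_recurrent))
})

test_that("microsimulation oracle agrees with the cohort model", {
  # degenerate process: deterministic initial state and no transitions
  quiet <- transition_params(p_excess_death_mrs02 = 0,
                             p_excess_death_mrs35 = 0,
                             recurrence = recurrence_schedule(0, 0, 0, 0))
  cfg <- toy_config(transitions = quiet, qx = 0, max_age = 80)
  d90 <- mrs_distribution(1, 0, 0)
  tr <- run_cohort(d90, cfg)
  cohort <- accumulate_outcomes(tr, cfg$utilities, cfg$costs,
                                cfg$discount_rate)
  ms <- microsim_oracle(d90, cfg, 500, seed = 1)
  expect_equal(ms$total_qalys, cohort$total_qalys, tolerance = 1e-9)
  expect_equal(ms$total_cost, cohort$total_cost, tolerance = 1e-9)

  # same seed reproduces the estimate bit for bit
  ms2 <- microsim_oracle(d90, cfg, 500, seed = 1)
  expect_identical(ms, ms2)

  # stochastic case within 3 Monte-Carlo standard errors
  cfg2 <- generate_country_config(generator_params(8))
  d2 <- mix_90day_distribution(arm_mix_from_profile(cfg2$profile),
                               cfg2$outcomes)
  tr2 <- run_cohort(d2, cfg2)
  c2 <- accumulate_outcomes(tr2, cfg2$utilities, cfg2$costs,
                            cfg2$discount_rate)
  ms3 <- microsim_oracle(d2, cfg2, 20000, seed = 77)
  expect_lt(abs(ms3$total_qalys - c2$total_qalys), 3 * ms3$se_qalys)
  expect_lt(abs(ms3$total_cost - c2$total_cost), 3 * ms3$se_cost)
})

test_that("the recurrence clock convention changes the projection only via recurrence", {
  cfg <- generate_country_config(generator_params(12))
  d90 <- mix_90day_distribution(arm_mix_from_profile(cfg$profile),
                                cfg$outcomes)
  tr_fixed <- run_cohort(d90, cfg, reset_clock = FALSE)
  tr_reset <- run_cohort(d90, cfg, reset_clock = TRUE)
  # resetting the clock re-exposes survivors of a recurrent event to the
  # higher early-year hazards, so recurrent person-years cannot fall
  expect_gte(sum(tr_reset$occ_recurrent), sum(tr_fixed$occ_recurrent))
  # and the microsimulation agrees under the same convention
  cc <- accumulate_outcomes(tr_reset, cfg$utilities, cfg$costs,
                            cfg$discount_rate)
  ms <- microsim_oracle(d90, cfg, 20000, seed = 5, reset_clock = TRUE)
  expect_lt(abs(ms$total_qalys - cc$total_qalys), 3 * ms$se_qalys)
})
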