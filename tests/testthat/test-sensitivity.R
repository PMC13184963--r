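# Deterministic (tornado) and probabilistic sensitivity analysis.

test_that("config paths read and write parameters with simplex rebalancing", {
  cfg <- toy_config()
  expect_equal(config_get(cfg, "transitions.recurrence.p_year1"), 0.111)
  expect_equal(config_get(cfg, "outcomes.standard.p_mrs02"), 0.22)

  # swinging a simplex component rebalances the residual bin
  cfg2 <- config_set(cfg, "outcomes.standard.p_mrs02", 0.25)
  d <- cfg2$outcomes$standard
  expect_equal(d[["p_mrs02"]], 0.25)
  expect_equal(d[["p_mrs6"]], 0.23)   # untouched
  expect_equal(d[["p_mrs35"]], 0.52)  # residual
  expect_simplex(d)

  cfg3 <- config_set(cfg, "transitions.recurrent_exit.p_death", 0.16)
  ex <- cfg3$transitions$recurrent_exit
  expect_equal(ex[["p_death"]], 0.16)
  expect_equal(ex[["p_mrs02"]], 0.25)
  expect_equal(sum(ex), 1, tolerance = 1e-12)

  cfg4 <- config_set(cfg, "utilities.u_mrs35", 0.21)
  expect_equal(cfg4$utilities$u_mrs35, 0.21)

  expect_error(config_get(cfg, "outcomes.nonsense.p"), "nonsense")
  expect_error(config_set(cfg, "utilities.u_mrs35", 1.5), "u_mrs35")
})

test_that("DSA with ranges collapsed to base reproduces the base case", {
  cfg <- toy_config()
  spec <- scenario_spec(2)
  base <- run_comparison(cfg, spec)
  ranges <- list(
    dsa_range("utilities.u_mrs02", 0.71, 0.71),
    dsa_range("transitions.recurrence.p_year1", 0.111, 0.111))
  tor <- one_way_dsa(cfg, spec, ranges)
  expect_equal(tor$inc_qalys_low, rep(base$econ$inc_qalys, 2),
               tolerance = 1e-12)
  expect_equal(tor$inc_qalys_high, tor$inc_qalys_low, tolerance = 1e-12)
  expect_equal(tor$swing_qalys, c(0, 0))
})

test_that("tornado ordering is a permutation sorted by QALY swing", {
  cfg <- toy_config()
  spec <- scenario_spec(2)
  ranges <- default_dsa_ranges(cfg)
  tor <- one_way_dsa(cfg, spec, ranges)
  expect_setequal(tor$parameter,
                  vapply(ranges, `[[`, "", "parameter"))
  expect_equal(nrow(tor), length(ranges))
  expect_true(all(diff(tor$swing_qalys) <= 1e-15))
  expect_false(any(tor$failed))
  # a zero-width range ranks last
  tor2 <- one_way_dsa(cfg, spec, c(ranges,
                                   list(dsa_range("utilities.u_mrs02",
                                                  0.71, 0.71))))
  expect_equal(tor2$swing_qalys[nrow(tor2)], 0)
})

test_that("short-term QALY swings are led by the outcome of an arm the target moves", {
  # for a rate target the increment is the moved share times the
  # (destination - standard) outcome gap, so the widest bars belong to the
  # two arms the shift connects
  cfg <- fixture_countries()$Italy
  spec <- scenario_spec(2)
  short_term <- c("outcomes.standard.p_mrs02", "outcomes.standard.p_mrs6",
                  "outcomes.ivt.p_mrs02", "outcomes.ivt.p_mrs6",
                  "outcomes.evt.p_mrs02", "outcomes.evt.p_mrs6")
  tor <- one_way_dsa(cfg, spec, lapply(short_term, function(p) {
    base <- config_get(cfg, p)
    dsa_range(p, base * 0.9, base * 1.1)
  }))
  expect_true(tor$parameter[1] %in% c("outcomes.standard.p_mrs02",
                                      "outcomes.evt.p_mrs02"))
  # the untouched IVT arm never leads the tornado
  expect_false(grepl("^outcomes.ivt", tor$parameter[1]))
})

test_that("incremental QALYs move monotonically across the mortality OR range", {
  cfg <- fixture_countries()$France
  spec <- scenario_spec(4)
  ors <- c(1.05, 1.10, 1.16, 1.22, 1.28)
  qal <- vapply(ors, function(or) {
    run_comparison(config_set(cfg, "acute_effects.mortality_or_per_hour", or),
                   spec)$econ$inc_qalys
  }, numeric(1))
  expect_true(all(diff(qal) > 0) || all(diff(qal) < 0))
})

test_that("infeasible swings are recorded as failed evaluations, not crashes", {
  cfg <- toy_config()
  tor <- one_way_dsa(cfg, scenario_spec(2),
                     list(dsa_range("transitions.recurrence.p_year1",
                                    0.111, 2))) # invalid probability
  expect_true(tor$failed[1])
  expect_true(is.na(tor$inc_qalys_high[1]))
  expect_false(is.na(tor$inc_qalys_low[1]))
})

test_that("PSA betas use the 1000-sample parameterisation", {
  cfg <- toy_config()
  draws <- sample_psa(psa_spec(n_draws = 10000, seed = 42), cfg)
  p02 <- vapply(draws, function(d) d$outcomes$standard[["p_mrs02"]],
                numeric(1))
  # beta(220, 780): mean 0.22, sd about 0.013
  expect_lt(abs(mean(p02) - 0.22), 0.005)
  expect_lt(abs(sd(p02) - sqrt(0.22 * 0.78 / 1001)), 0.003)
})

test_that("every sampled simplex block is valid and the sequence is seed-reproducible", {
  cfg <- toy_config()
  spec <- psa_spec(n_draws = 10000, seed = 7)
  draws <- sample_psa(spec, cfg)
  for (d in draws[seq(1, 10000, by = 97)]) {
    for (arm in c("standard", "ivt", "evt")) expect_simplex(d$outcomes[[arm]])
    expect_equal(sum(d$recurrent_exit), 1, tolerance = 1e-9)
    expect_true(all(d$recurrent_exit >= 0))
    expect_true(d$recurrence[["p_year1"]] >= d$recurrence[["p_years2_5"]])
  }
  sums <- vapply(draws, function(d) {
    sum(unclass(d$outcomes$standard)) + sum(d$recurrent_exit)
  }, numeric(1))
  expect_true(all(abs(sums - 2) < 1e-9))

  draws2 <- sample_psa(psa_spec(n_draws = 10000, seed = 7), cfg)
  expect_identical(draws, draws2)
  draws3 <- sample_psa(psa_spec(n_draws = 10, seed = 8), cfg)
  expect_false(identical(draws[1:10], draws3))
})

test_that("the Dirichlet sampler produces valid simplexes with matching means", {
  cfg <- toy_config()
  draws <- sample_psa(psa_spec(n_draws = 2000, seed = 3,
                               sampler = "dirichlet"), cfg)
  p02 <- vapply(draws, function(d) d$outcomes$standard[["p_mrs02"]],
                numeric(1))
  expect_lt(abs(mean(p02) - 0.22), 0.005)
  for (d in draws[1:20]) expect_simplex(d$outcomes$standard)
})

test_that("PSA cloud collapses to the base case and CEAC is monotone", {
  cfg <- toy_config(max_age = 90)
  spec <- scenario_spec(2)
  res <- run_psa(cfg, spec, psa_spec(n_draws = 150, seed = 11),
                 thresholds = seq(0, 50000, by = 10000))
  expect_equal(res$n_failed, 0)
  base <- run_comparison(cfg, spec)
  # consistency: PSA mean within Monte-Carlo error of the base case
  se_q <- sd(res$cloud$inc_qalys) / sqrt(nrow(res$cloud))
  expect_lt(abs(res$summary$mean_inc_qalys - base$econ$inc_qalys), 4 * se_q)
  # CEAC: all draws gain QALYs here, so higher thresholds never hurt
  expect_true(all(res$cloud$inc_qalys > 0))
  expect_true(all(diff(res$ceac$p_cost_effective) >= 0))
  expect_true(all(res$ceac$p_cost_effective >= 0 &
                    res$ceac$p_cost_effective <= 1))
})
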