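# Lifetime Markov cohort model over {mRS 0-2, mRS 3-5, recurrent stroke,
# dead}. Cycle length is one year; the first cycle begins at day 90 after the
# index stroke and is treated as a full year for rewards. Background
# life-table mortality and stroke-related excess mortality are combined as
# independent competing risks, 1 - (1-a)(1-b). The recurrent-stroke state is
# a strict one-cycle tunnel redistributed to (mRS 0-2, mRS 3-5, death).
#
# Occupancy is tracked per "clock bin" (years since the most recent stroke,
# capped at 11 = "beyond year 10"), which lets the recurrence clock either
# run from the index stroke (default) or reset after a recurrent event.

CLOCK_CAP <- 11L

recurrence_at <- function(schedule, years_since_stroke) {
  k <- pmin(pmax(as.integer(years_since_stroke), 1L), CLOCK_CAP)
  probs <- c(schedule$p_year1, rep(schedule$p_years2_5, 4L),
             rep(schedule$p_years6_10, 5L), schedule$p_beyond10)
  probs[k]
}

combine_mortality <- function(a, b) 1 - (1 - a) * (1 - b)

#' One annual transition-probability row
#'
#' Probability row over (mRS 0-2, mRS 3-5, recurrent, dead) for a live state.
#' For the mRS bands, recurrence follows the time-since-stroke schedule,
#' death combines stroke-related excess mortality with background `qx(age)`
#' as independent competing risks, staying is the remainder, and there is no
#' direct crossing between mRS 0-2 and mRS 3-5. For the recurrent tunnel the
#' exit distribution is applied with its death component likewise combined
#' with background mortality (the two live exits keep their relative
#' proportions). When `qx(age) = 1` (the life-table closure age) the row is
#' certain death.
#'
#' @param state `"mrs02"`, `"mrs35"` or `"recurrent"`.
#' @param years_since_stroke whole years since the most recent stroke (the
#'   first post-stroke year is 1).
#' @param age current age in years.
#' @param params a [transition_params()].
#' @param life_table a [life_table()].
#' @return Named numeric vector over `mrs02`, `mrs35`, `recurrent`, `dead`,
#'   summing to 1.
#' @export
transition_row <- function(state, years_since_stroke, age, params, life_table) {
  state <- match.arg(state, c("mrs02", "mrs35", "recurrent"))
  qx <- qx_at(life_table, age)
  if (qx >= 1) {
    return(c(mrs02 = 0, mrs35 = 0, recurrent = 0, dead = 1))
  }
  if (state == "recurrent") {
    ex <- params$recurrent_exit
    p_death <- combine_mortality(ex[["p_death"]], qx)
    live <- ex[["p_mrs02"]] + ex[["p_mrs35"]]
    share02 <- if (live > 0) ex[["p_mrs02"]] / live else 0
    return(c(mrs02 = (1 - p_death) * share02,
             mrs35 = (1 - p_death) * (1 - share02),
             recurrent = 0, dead = p_death))
  }
  excess <- if (state == "mrs02") params$p_excess_death_mrs02 else
    params$p_excess_death_mrs35
  p_death <- combine_mortality(excess, qx)
  p_rec <- recurrence_at(params$recurrence, years_since_stroke)
  p_stay <- 1 - p_death - p_rec
  if (p_stay < -1e-12) {
    stopf("transition row infeasible for %s (year %d, age %g): recurrence %.4g + death %.4g > 1",
          state, as.integer(years_since_stroke), age, p_rec, p_death)
  }
  p_stay <- max(p_stay, 0)
  if (state == "mrs02") {
    c(mrs02 = p_stay, mrs35 = 0, recurrent = p_rec, dead = p_death)
  } else {
    c(mrs02 = 0, mrs35 = p_stay, recurrent = p_rec, dead = p_death)
  }
}

#' Project a cohort through the lifetime Markov model
#'
#' Forward cohort projection starting at day 90 with the given 90-day mRS
#' distribution (mRS 6 enters as already dead). Runs to the life-table
#' closure age by default, at which the cohort is fully absorbed into death.
#'
#' @param initial the 90-day [mrs_distribution()].
#' @param config a [country_config()].
#' @param horizon number of yearly cycles; default runs until the cohort
#'   reaches the life-table `max_age`.
#' @param reset_clock should the recurrence clock restart after a recurrent
#'   event? Default `FALSE`: one clock from the index stroke.
#' @return A data frame of class `cohort_trace` with per-cycle columns
#'   `cycle`, `age`, `occ_mrs02`, `occ_mrs35`, `occ_recurrent`, `occ_dead`
#'   and `rec_entries` (mass entering the recurrent tunnel that cycle).
#' @export
run_cohort <- function(initial, config, horizon = NULL, reset_clock = FALSE) {
  initial <- as_mrs_distribution(initial)
  stopifnot(inherits(config, "country_config"))
  start_age <- config$cohort_start_age
  lt <- config$life_table
  # one cycle beyond the closure age so the recorded trace ends fully
  # absorbed into death
  n_cycles <- if (is.null(horizon)) {
    as.integer(lt$max_age - floor(start_age) + 2)
  } else {
    check_number(horizon, "horizon", 1, Inf)
    as.integer(horizon)
  }

  # occupancy by clock bin (rows) and live mRS band (cols)
  occ <- matrix(0, CLOCK_CAP, 2L, dimnames = list(NULL, c("mrs02", "mrs35")))
  occ[1L, ] <- c(initial[["p_mrs02"]], initial[["p_mrs35"]])
  rec <- 0
  dead <- initial[["p_mrs6"]]

  cols <- c("occ_mrs02", "occ_mrs35", "occ_recurrent", "occ_dead",
            "rec_entries")
  out <- matrix(0, n_cycles, length(cols), dimnames = list(NULL, cols))
  params <- config$transitions

  for (t in seq_len(n_cycles)) {
    total <- sum(occ) + rec + dead
    if (abs(total - 1) > 1e-9) {
      stopf("occupancy conservation violated at cycle %d (sum %.12g)", t, total)
    }
    out[t, ] <- c(sum(occ[, 1L]), sum(occ[, 2L]), rec, dead, rec)

    age <- start_age + t - 1
    new_occ <- matrix(0, CLOCK_CAP, 2L)
    new_rec <- 0
    for (k in seq_len(CLOCK_CAP)) {
      k_next <- min(k + 1L, CLOCK_CAP)
      if (occ[k, 1L] > 0) {
        row <- transition_row("mrs02", k, age, params, lt)
        new_occ[k_next, 1L] <- new_occ[k_next, 1L] + occ[k, 1L] * row[["mrs02"]]
        new_rec <- new_rec + occ[k, 1L] * row[["recurrent"]]
        dead <- dead + occ[k, 1L] * row[["dead"]]
      }
      if (occ[k, 2L] > 0) {
        row <- transition_row("mrs35", k, age, params, lt)
        new_occ[k_next, 2L] <- new_occ[k_next, 2L] + occ[k, 2L] * row[["mrs35"]]
        new_rec <- new_rec + occ[k, 2L] * row[["recurrent"]]
        dead <- dead + occ[k, 2L] * row[["dead"]]
      }
    }
    if (rec > 0) {
      row <- transition_row("recurrent", 1L, age, params, lt)
      k_exit <- if (reset_clock) 1L else min(t + 1L, CLOCK_CAP)
      new_occ[k_exit, 1L] <- new_occ[k_exit, 1L] + rec * row[["mrs02"]]
      new_occ[k_exit, 2L] <- new_occ[k_exit, 2L] + rec * row[["mrs35"]]
      dead <- dead + rec * row[["dead"]]
    }
    occ <- new_occ
    rec <- new_rec
  }

  trace <- data.frame(cycle = seq_len(n_cycles),
                      age = start_age + seq_len(n_cycles) - 1,
                      out)
  class(trace) <- c("cohort_trace", "data.frame")
  attr(trace, "reset_clock") <- reset_clock
  trace
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Per-cycle rewards are occupancy-weighted: live mRS bands accrue their
#' annual utility and annual care cost; recurrent-tunnel occupants accrue the
#' recurrent-year utility plus the one-off recurrent event cost (the tunnel
#' lasts exactly one cycle, so occupancy equals entries). Cycle `t` is
#' discounted by `1/(1+r)^t` (end-of-cycle convention), with `t` counted in
#' whole years from the index stroke.
#'
#' @param trace a [run_cohort()] trace.
#' @param utilities a [utility_set()].
#' @param costs a [cost_set()].
#' @param discount_rate annual discount rate.
#' @return A list of class `lifetime_result`: `total_cost`, `total_qalys`,
#'   `life_years` (discounted), an `undiscounted` list of the same three,
#'   and the discounted per-cycle streams `cycle_costs` and `cycle_qalys`.
#' @export
accumulate_outcomes <- function(trace, utilities, costs, discount_rate) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(utilities, "utility_set"), inherits(costs, "cost_set"))
  r <- check_number(discount_rate, "discount_rate", 0, 0.1)
  disc <- (1 + r)^(-trace$cycle)
  qaly_t <- trace$occ_mrs02 * utilities$u_mrs02 +
    trace$occ_mrs35 * utilities$u_mrs35 +
    trace$occ_recurrent * utilities$u_recurrent_year
  cost_t <- trace$occ_mrs02 * costs$annual_cost_mrs02 +
    trace$occ_mrs35 * costs$annual_cost_mrs35 +
    trace$rec_entries * costs$recurrent_event_cost
  ly_t <- trace$occ_mrs02 + trace$occ_mrs35 + trace$occ_recurrent
  if (any(qaly_t < 0) || any(cost_t < 0)) {
    stopf("negative per-cycle rewards are not allowed")
  }
  structure(list(
    total_cost = sum(cost_t * disc),
    total_qalys = sum(qaly_t * disc),
    life_years = sum(ly_t * disc),
    undiscounted = list(total_cost = sum(cost_t),
                        total_qalys = sum(qaly_t),
                        life_years = sum(ly_t)),
    cycle_costs = cost_t * disc,
    cycle_qalys = qaly_t * disc
  ), class = "lifetime_result")
}

#' Export a cohort trace with reward streams for audit
#'
#' @param trace a [run_cohort()] trace.
#' @param result the matching [accumulate_outcomes()] result.
#' @param path destination of the tab-delimited table.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, result, path) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(result, "lifetime_result"))
  df <- data.frame(cycle = trace$cycle, age = trace$age,
                   occ_mrs02 = trace$occ_mrs02, occ_mrs35 = trace$occ_mrs35,
                   occ_recurrent = trace$occ_recurrent,
                   occ_dead = trace$occ_dead,
                   disc_cost = result$cycle_costs,
                   disc_qaly = result$cycle_qalys)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Individual-level microsimulation oracle
#'
#' Simulates the identical yearly process patient by patient and reports
#' Monte-Carlo estimates of the discounted lifetime totals with standard
#' errors. Used to validate the deterministic cohort projection; the two
#' must agree within Monte-Carlo error.
#'
#' @param initial the 90-day [mrs_distribution()].
#' @param config a [country_config()].
#' @param n_patients number of simulated patients.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @param reset_clock as in [run_cohort()].
#' @return A list of class `microsim_result` with means (`total_cost`,
#'   `total_qalys`, `life_years`), standard errors (`se_cost`, `se_qalys`,
#'   `se_life_years`) and `n_patients`.
#' @export
microsim_oracle <- function(initial, config, n_patients, seed,
                            reset_clock = FALSE) {
  initial <- as_mrs_distribution(initial)
  stopifnot(inherits(config, "country_config"))
  n <- as.integer(check_number(n_patients, "n_patients", 1, Inf))
  params <- config$transitions
  lt <- config$life_table
  ut <- config$utilities
  cs <- config$costs
  r <- config$discount_rate
  start_age <- config$cohort_start_age
  n_cycles <- as.integer(lt$max_age - floor(start_age) + 2)

  sched <- c(params$recurrence$p_year1, rep(params$recurrence$p_years2_5, 4L),
             rep(params$recurrence$p_years6_10, 5L),
             params$recurrence$p_beyond10)
  ex <- params$recurrent_exit
  live_exit <- ex[["p_mrs02"]] + ex[["p_mrs35"]]
  share02 <- if (live_exit > 0) ex[["p_mrs02"]] / live_exit else 0

  with_seed(seed, {
    u0 <- runif(n)
    # 1 = mrs02, 2 = mrs35, 3 = recurrent, 4 = dead
    state <- ifelse(u0 < initial[["p_mrs02"]], 1L,
                    ifelse(u0 < initial[["p_mrs02"]] + initial[["p_mrs35"]],
                           2L, 4L))
    clock <- rep(1L, n)
    qaly <- numeric(n)
    cost <- numeric(n)
    ly <- numeric(n)

    for (t in seq_len(n_cycles)) {
      disc <- (1 + r)^(-t)
      qaly <- qaly + disc * ((state == 1L) * ut$u_mrs02 +
                               (state == 2L) * ut$u_mrs35 +
                               (state == 3L) * ut$u_recurrent_year)
      cost <- cost + disc * ((state == 1L) * cs$annual_cost_mrs02 +
                               (state == 2L) * cs$annual_cost_mrs35 +
                               (state == 3L) * cs$recurrent_event_cost)
      ly <- ly + disc * (state != 4L)

      age <- start_age + t - 1
      qx <- qx_at(lt, age)
      if (qx >= 1) {
        state[] <- 4L
        next
      }
      u <- runif(n)
      new_state <- state
      for (s in 1:2) {
        idx <- which(state == s)
        if (!length(idx)) next
        excess <- if (s == 1L) params$p_excess_death_mrs02 else
          params$p_excess_death_mrs35
        p_death <- combine_mortality(excess, qx)
        p_rec <- sched[pmin(clock[idx], CLOCK_CAP)]
        if (any(p_rec + p_death > 1 + 1e-12)) {
          stopf("transition row infeasible at age %g", age)
        }
        ui <- u[idx]
        new_state[idx] <- ifelse(ui < p_rec, 3L,
                                 ifelse(ui < p_rec + p_death, 4L, s))
      }
      idx <- which(state == 3L)
      if (length(idx)) {
        p_death <- combine_mortality(ex[["p_death"]], qx)
        ui <- u[idx]
        new_state[idx] <- ifelse(ui < p_death, 4L,
                                 ifelse(ui < p_death + (1 - p_death) * share02,
                                        1L, 2L))
      }
      if (reset_clock) {
        clock <- clock + 1L
        clock[state == 3L & new_state %in% c(1L, 2L)] <- 1L
      } else {
        clock <- rep(min(t + 1L, CLOCK_CAP), n)
      }
      state <- new_state
    }

    structure(list(
      total_cost = mean(cost), total_qalys = mean(qaly),
      life_years = mean(ly),
      se_cost = sd(cost) / sqrt(n), se_qalys = sd(qaly) / sqrt(n),
      se_life_years = sd(ly) / sqrt(n),
      n_patients = n, seed = seed
    ), class = "microsim_result")
  })
}
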