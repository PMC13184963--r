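# One-way deterministic sensitivity analysis (tornado ordering) and
# probabilistic sensitivity analysis with constrained beta sampling.
#
# Parameters are addressed by dotted paths into the config
# (e.g. "outcomes.standard.p_mrs02"). When a swung parameter is a component
# of a probability simplex, the residual bin absorbs the change: mRS 3-5 for
# the outcome triples (mRS 0-2 for a swing of mRS 3-5 itself), and the death
# component of the recurrent-exit triple when its mRS 3-5 share is swung.

#' Read a parameter by dotted path
#' @param config a [country_config()].
#' @param path dotted path, e.g. `"transitions.recurrence.p_year1"`.
#' @return The parameter value.
#' @export
config_get <- function(config, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (p in parts) {
    if (is.null(node[[p]]) && !(p %in% names(node))) {
      stopf("no parameter at path '%s' (unknown component '%s')", path, p)
    }
    node <- node[[p]]
  }
  node
}

#' Set a parameter by dotted path, rebalancing simplexes
#'
#' Writes the value, rebalances the residual bin when the target lives in a
#' probability simplex, and re-validates the whole config; an invalid
#' result is an error (deterministic sensitivity analysis records such
#' swings as failed evaluations).
#'
#' @param config a [country_config()].
#' @param path dotted path as in [config_get()].
#' @param value new value.
#' @return The modified, validated config.
#' @export
config_set <- function(config, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  leaf <- parts[length(parts)]
  parent_path <- parts[-length(parts)]

  node <- config
  for (p in parent_path) node <- node[[p]]
  if (!(leaf %in% names(node)) && is.null(node[[leaf]])) {
    stopf("no parameter at path '%s'", path)
  }

  if (inherits(node, "mrs_distribution")) {
    v <- unclass(node)
    v[[leaf]] <- value
    residual <- if (leaf == "p_mrs35") "p_mrs02" else "p_mrs35"
    v[[residual]] <- 1 - sum(v[setdiff(MRS_BANDS, residual)])
    new_node <- mrs_distribution(v[["p_mrs02"]], v[["p_mrs35"]], v[["p_mrs6"]])
  } else if (identical(sort(names(node)), sort(c("p_mrs02", "p_mrs35", "p_death")))) {
    v <- node
    v[[leaf]] <- value
    residual <- if (leaf == "p_mrs35") "p_death" else "p_mrs35"
    v[[residual]] <- 1 - sum(v[setdiff(names(v), residual)])
    new_node <- v
  } else {
    new_node <- node
    new_node[[leaf]] <- value
  }

  out <- assign_path(config, parent_path, new_node)
  validate_country_config(out)
}

assign_path <- function(obj, parts, value) {
  if (!length(parts)) return(value)
  cls <- class(obj)
  obj[[parts[1]]] <- assign_path(obj[[parts[1]]], parts[-1], value)
  class(obj) <- cls
  obj
}

#' One parameter range for deterministic sensitivity analysis
#'
#' @param parameter dotted config path.
#' @param low,high range bounds with `low <= high`.
#' @return A list of class `dsa_range`.
#' @export
dsa_range <- function(parameter, low, high) {
  if (low > high) stopf("dsa_range for '%s': low %g > high %g", parameter,
                        low, high)
  structure(list(parameter = parameter, low = low, high = high),
            class = "dsa_range")
}

#' Default one-way ranges
#'
#' The published ranges where they exist (transition probabilities, the
#' mortality OR confidence interval 1.05-1.28, utilities), and plus/minus
#' 10% of the base value elsewhere (the pattern of the published ranges).
#'
#' @param config a [country_config()].
#' @return A list of [dsa_range()] objects.
#' @export
default_dsa_ranges <- function(config) {
  pm10 <- function(path) {
    base <- config_get(config, path)
    dsa_range(path, base * 0.9, base * 1.1)
  }
  c(
    lapply(c("outcomes.standard.p_mrs02", "outcomes.standard.p_mrs6",
             "outcomes.ivt.p_mrs02", "outcomes.ivt.p_mrs6",
             "outcomes.evt.p_mrs02", "outcomes.evt.p_mrs6",
             "acute_effects.ard_per_minute",
             "costs.annual_cost_mrs02", "costs.annual_cost_mrs35",
             "costs.recurrent_event_cost"), pm10),
    list(
      dsa_range("acute_effects.mortality_or_per_hour", 1.05, 1.28),
      dsa_range("transitions.p_excess_death_mrs02", 0.0072, 0.0088),
      dsa_range("transitions.p_excess_death_mrs35", 0.0351, 0.0429),
      dsa_range("transitions.recurrence.p_year1", 0.0999, 0.1221),
      dsa_range("transitions.recurrence.p_years2_5", 0.0366, 0.0448),
      dsa_range("transitions.recurrence.p_years6_10", 0.0243, 0.0297),
      dsa_range("transitions.recurrent_exit.p_mrs02", 0.2250, 0.2750),
      dsa_range("transitions.recurrent_exit.p_mrs35", 0.5445, 0.6655),
      dsa_range("transitions.recurrent_exit.p_death", 0.1305, 0.1595),
      dsa_range("utilities.u_mrs02", 0.70, 0.72),
      dsa_range("utilities.u_mrs35", 0.19, 0.21)))
}

#' One-way deterministic sensitivity analysis with tornado ordering
#'
#' Swings each parameter alone to its low and high value, re-runs the full
#' baseline-vs-target comparison, and orders parameters by the magnitude of
#' their incremental-QALY swing (the incremental-cost swing is reported
#' alongside, as the paired tornado bars). Swings that produce an invalid
#' config or a failed run are recorded, not raised.
#'
#' @param config a [country_config()].
#' @param spec a [scenario_spec()].
#' @param ranges list of [dsa_range()]; defaults to [default_dsa_ranges()].
#' @return A data frame of class `tornado`, one row per parameter, ordered
#'   by decreasing `swing_qalys`, with the base-case increments in
#'   attributes `base_inc_cost` / `base_inc_qalys`.
#' @export
one_way_dsa <- function(config, spec, ranges = default_dsa_ranges(config)) {
  if (!length(ranges)) stopf("no ranges supplied")
  base <- run_comparison(config, spec)

  eval_at <- function(parameter, value) {
    tryCatch({
      cfg <- config_set(config, parameter, value)
      res <- run_comparison(cfg, spec)
      c(res$econ$inc_cost, res$econ$inc_qalys)
    }, error = function(e) c(NA_real_, NA_real_))
  }

  rows <- lapply(ranges, function(rg) {
    lo <- eval_at(rg$parameter, rg$low)
    hi <- eval_at(rg$parameter, rg$high)
    data.frame(parameter = rg$parameter, low = rg$low, high = rg$high,
               inc_cost_low = lo[1], inc_qalys_low = lo[2],
               inc_cost_high = hi[1], inc_qalys_high = hi[2],
               failed = anyNA(c(lo, hi)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$swing_qalys <- abs(out$inc_qalys_high - out$inc_qalys_low)
  out$swing_costs <- abs(out$inc_cost_high - out$inc_cost_low)
  ord <- order(-ifelse(is.na(out$swing_qalys), -Inf, out$swing_qalys))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_inc_cost") <- base$econ$inc_cost
  attr(out, "base_inc_qalys") <- base$econ$inc_qalys
  class(out) <- c("tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis specification
#'
#' Probabilities are drawn from beta distributions parameterised as
#' `alpha = 1000 p`, `beta = 1000 (1 - p)` (the mean frequency out of 1000
#' samples). Multinomial blocks (the three arm outcome triples and the
#' recurrent-exit triple) are sampled as independent constrained betas: the
#' free components are drawn and the draw is rejected unless the residual
#' bin stays inside \[0, 1\]. A Dirichlet sampler with the same
#' pseudo-counts is available for comparison.
#'
#' @param n_draws number of parameter draws (>= 1).
#' @param seed mandatory RNG seed.
#' @param vary_costs also draw costs (gamma with 20% coefficient of
#'   variation)? Off by default.
#' @param sampler `"beta_constrained"` (default) or `"dirichlet"`.
#' @param max_rejections cap on rejected draws per simplex block before the
#'   block is reported as infeasible.
#' @return A list of class `psa_spec`.
#' @export
psa_spec <- function(n_draws = 1000, seed, vary_costs = FALSE,
                     sampler = c("beta_constrained", "dirichlet"),
                     max_rejections = 10000) {
  sampler <- match.arg(sampler)
  structure(list(
    n_draws = as.integer(check_number(n_draws, "n_draws", 1, Inf)),
    seed = as.integer(check_number(seed, "seed")),
    vary_costs = isTRUE(vary_costs),
    sampler = sampler,
    max_rejections = as.integer(check_number(max_rejections,
                                             "max_rejections", 1, Inf))
  ), class = "psa_spec")
}

beta_1000 <- function(p) {
  if (p <= 0) return(0)
  if (p >= 1) return(1)
  rbeta(1L, 1000 * p, 1000 * (1 - p))
}

# Sample a (p_a, p_b, residual) simplex block; returns c(p_a, p_b, residual).
sample_simplex_block <- function(p_a, p_b, sampler, max_rejections, label) {
  if (sampler == "dirichlet") {
    g <- c(rgamma_safe(1000 * p_a), rgamma_safe(1000 * p_b),
           rgamma_safe(1000 * (1 - p_a - p_b)))
    return(g / sum(g))
  }
  for (i in seq_len(max_rejections)) {
    a <- beta_1000(p_a)
    b <- beta_1000(p_b)
    resid <- 1 - a - b
    if (resid >= 0 && resid <= 1) return(c(a, b, resid))
  }
  stopf("simplex block '%s' rejected %d consecutive draws", label,
        max_rejections)
}

rgamma_safe <- function(shape) if (shape <= 0) 0 else stats::rgamma(1L, shape)

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' @param spec a [psa_spec()].
#' @param config the base [country_config()] providing the means.
#' @return A list of `n_draws` parameter draws; each draw holds the three
#'   arm outcome distributions, transition parameters and utilities (plus
#'   costs when `vary_costs`). Reproducible given the seed.
#' @export
sample_psa <- function(spec, config) {
  stopifnot(inherits(spec, "psa_spec"), inherits(config, "country_config"))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_draws), function(i) draw_one(spec, config))
  })
}

draw_one <- function(spec, config) {
  draw <- list()
  for (arm in TREATMENT_ARMS) {
    d <- config$outcomes[[arm]]
    blk <- sample_simplex_block(d[["p_mrs02"]], d[["p_mrs6"]], spec$sampler,
                                spec$max_rejections,
                                paste0("outcomes.", arm))
    draw$outcomes[[arm]] <- mrs_distribution(blk[1], blk[3], blk[2])
  }
  ex <- config$transitions$recurrent_exit
  blk <- sample_simplex_block(ex[["p_mrs02"]], ex[["p_mrs35"]], spec$sampler,
                              spec$max_rejections, "recurrent_exit")
  draw$recurrent_exit <- c(p_mrs02 = blk[1], p_mrs35 = blk[2],
                           p_death = blk[3])
  tr <- config$transitions
  draw$p_excess_death_mrs02 <- beta_1000(tr$p_excess_death_mrs02)
  draw$p_excess_death_mrs35 <- beta_1000(tr$p_excess_death_mrs35)
  rec <- tr$recurrence
  # recurrence periods drawn independently, resampled into monotone order
  repeat {
    r1 <- beta_1000(rec$p_year1)
    r2 <- beta_1000(rec$p_years2_5)
    r3 <- beta_1000(rec$p_years6_10)
    if (r1 >= r2 && r2 >= r3) break
  }
  draw$recurrence <- c(p_year1 = r1, p_years2_5 = r2, p_years6_10 = r3,
                       p_beyond10 = rec$p_beyond10)
  ut <- config$utilities
  draw$u_mrs02 <- beta_1000(ut$u_mrs02)
  draw$u_mrs35 <- beta_1000(ut$u_mrs35)
  if (spec$vary_costs) {
    cv <- 0.2
    shape <- 1 / cv^2
    gdraw <- function(mean) if (mean <= 0) 0 else
      stats::rgamma(1L, shape = shape, rate = shape / mean)
    cs <- config$costs
    draw$costs <- list(annual_cost_mrs02 = gdraw(cs$annual_cost_mrs02),
                       annual_cost_mrs35 = gdraw(cs$annual_cost_mrs35),
                       recurrent_event_cost = gdraw(cs$recurrent_event_cost))
  }
  draw
}

#' Apply one PSA draw to a configuration
#' @param config a [country_config()].
#' @param draw one element of [sample_psa()]'s result.
#' @return The config with the drawn parameters substituted.
#' @export
apply_psa_draw <- function(config, draw) {
  cfg <- config
  cfg$outcomes <- outcome_table(draw$outcomes$standard, draw$outcomes$ivt,
                                draw$outcomes$evt)
  cfg$transitions <- transition_params(
    p_excess_death_mrs02 = draw$p_excess_death_mrs02,
    p_excess_death_mrs35 = draw$p_excess_death_mrs35,
    recurrence = recurrence_schedule(draw$recurrence[["p_year1"]],
                                     draw$recurrence[["p_years2_5"]],
                                     draw$recurrence[["p_years6_10"]],
                                     draw$recurrence[["p_beyond10"]]),
    recurrent_exit = draw$recurrent_exit)
  cfg$utilities <- utility_set(u_mrs02 = draw$u_mrs02,
                               u_mrs35 = draw$u_mrs35)
  if (!is.null(draw$costs)) {
    cfg$costs$annual_cost_mrs02 <- draw$costs$annual_cost_mrs02
    cfg$costs$annual_cost_mrs35 <- draw$costs$annual_cost_mrs35
    cfg$costs$recurrent_event_cost <- draw$costs$recurrent_event_cost
  }
  cfg
}

#' Run a probabilistic sensitivity analysis
#'
#' Evaluates the full baseline-vs-target comparison under each parameter
#' draw (the same draw feeds both arms, so parameter uncertainty is fully
#' correlated across arms) and summarises the incremental cost/QALY cloud.
#'
#' @param config a [country_config()].
#' @param spec a [scenario_spec()].
#' @param psa a [psa_spec()].
#' @param thresholds willingness-to-pay grid (euros/QALY) for the
#'   cost-effectiveness acceptability curve.
#' @return A list of class `psa_result`: `cloud` (draw, inc_cost,
#'   inc_qalys), `summary` (means and 95% credible intervals), `ceac`
#'   (threshold, probability cost-effective) and `n_failed`.
#' @export
run_psa <- function(config, spec, psa,
                    thresholds = seq(0, 100000, by = 5000)) {
  draws <- sample_psa(psa, config)
  res <- lapply(seq_along(draws), function(i) {
    tryCatch({
      cfg <- apply_psa_draw(config, draws[[i]])
      r <- run_comparison(cfg, spec)
      c(r$econ$inc_cost, r$econ$inc_qalys)
    }, error = function(e) c(NA_real_, NA_real_))
  })
  m <- do.call(rbind, res)
  cloud <- data.frame(draw = seq_along(draws), inc_cost = m[, 1],
                      inc_qalys = m[, 2])
  ok <- stats::complete.cases(cloud)
  cl <- cloud[ok, , drop = FALSE]
  qs <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  summary <- list(
    mean_inc_cost = mean(cl$inc_cost), mean_inc_qalys = mean(cl$inc_qalys),
    ci_inc_cost = qs(cl$inc_cost), ci_inc_qalys = qs(cl$inc_qalys),
    n_draws = nrow(cloud), n_used = nrow(cl))
  ceac <- data.frame(
    threshold = thresholds,
    p_cost_effective = vapply(thresholds, function(wtp) {
      mean(wtp * cl$inc_qalys - cl$inc_cost >= 0)
    }, numeric(1)))
  structure(list(cloud = cloud, summary = summary, ceac = ceac,
                 n_failed = sum(!ok)),
            class = "psa_result")
}

#' Export PSA cloud or tornado results as delimited tables
#' @param x a `psa_result` or `tornado` object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
export_sensitivity <- function(x, path) {
  df <- if (inherits(x, "psa_result")) x$cloud else as.data.frame(x)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
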