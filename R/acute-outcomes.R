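# The 90-day decision tree: arm mixing and acute-effect operators.
#
# Treatment-rate targets move patients from the standard-care arm to a
# reperfusion arm; time targets improve the outcome distribution of the
# treated arm itself (onset-to-needle acts on IVT patients, onset-to-puncture
# on EVT patients). mRS 3-5 is always the residual bin so that the mRS 0-2
# gain and the mRS 3-5 loss mirror each other when the mortality odds ratio
# is 1.

#' Treatment-arm mix of the incident cohort
#'
#' @param share_standard,share_ivt,share_evt non-negative arm shares summing
#'   to 1.
#' @return A named numeric vector of class `arm_mix`.
#' @export
arm_mix <- function(share_standard, share_ivt, share_evt) {
  x <- c(standard = check_probability(share_standard, "share_standard"),
         ivt = check_probability(share_ivt, "share_ivt"),
         evt = check_probability(share_evt, "share_evt"))
  if (abs(sum(x) - 1) > 1e-9) {
    stopf("arm shares must sum to 1; got sum %.12g", sum(x))
  }
  structure(x, class = "arm_mix")
}

#' Arm mix implied by a treatment profile
#' @param profile a [treatment_profile()].
#' @return An [arm_mix()]; the standard-care share is the remainder.
#' @export
arm_mix_from_profile <- function(profile) {
  arm_mix(standard_care_share(profile), profile$ivt_rate, profile$evt_rate)
}

#' Cohort-level 90-day outcome distribution
#'
#' Convex combination of the arm-level outcome distributions weighted by the
#' arm mix.
#'
#' @param mix an [arm_mix()].
#' @param outcomes an [outcome_table()].
#' @return An [mrs_distribution()] for the whole cohort.
#' @examples
#' tab <- outcome_table(standard = mrs_distribution(0.22, 0.55, 0.23),
#'                      ivt = mrs_distribution(0.27, 0.54, 0.19),
#'                      evt = mrs_distribution(0.46, 0.40, 0.14))
#' mix_90day_distribution(arm_mix(0.773, 0.175, 0.052), tab)
#' @export
mix_90day_distribution <- function(mix, outcomes) {
  stopifnot(inherits(mix, "arm_mix"), inherits(outcomes, "outcome_table"))
  v <- mix[["standard"]] * unclass(outcomes$standard) +
    mix[["ivt"]] * unclass(outcomes$ivt) +
    mix[["evt"]] * unclass(outcomes$evt)
  mrs_distribution(v[["p_mrs02"]], v[["p_mrs35"]], v[["p_mrs6"]])
}

#' Raise a treatment rate to a target level
#'
#' Moves the increment entirely out of the standard-care share; the other
#' reperfusion arm is untouched. If the target rate is below the current
#' rate the target is already met and a condition of class
#' `strokecea_target_met` is signalled (callers report NA for such cells).
#'
#' @param profile a [treatment_profile()].
#' @param arm `"ivt"` or `"evt"`.
#' @param target_rate target arm rate as a fraction of the cohort.
#' @return The shifted [treatment_profile()] (unchanged when
#'   `target_rate` equals the current rate).
#' @export
apply_rate_shift <- function(profile, arm = c("ivt", "evt"), target_rate) {
  arm <- match.arg(arm)
  target_rate <- check_probability(target_rate, "target_rate")
  field <- paste0(arm, "_rate")
  current <- profile[[field]]
  if (target_rate < current - 1e-12) {
    cond <- structure(
      class = c("strokecea_target_met", "error", "condition"),
      list(message = sprintf(
        "%s rate %.4g already exceeds the %.4g target", arm, current,
        target_rate), call = NULL))
    stop(cond)
  }
  increment <- target_rate - current
  if (increment > standard_care_share(profile) + 1e-12) {
    stopf("raising the %s rate to %.4g needs %.4g more than the %.4g standard-care share",
          arm, target_rate, increment, standard_care_share(profile))
  }
  profile[[field]] <- target_rate
  validate <- treatment_profile(profile$ivt_rate, profile$evt_rate,
                                profile$otn_minutes, profile$otp_minutes)
  validate
}

#' Minutes saved by meeting a time-to-treatment threshold
#'
#' Targets are strict ("below the threshold"), honoured by aiming one minute
#' under it: `max(0, baseline - (threshold - 1))`. A baseline already under
#' the threshold saves nothing.
#'
#' @param baseline_minutes current representative onset-to-treatment time.
#' @param threshold_minutes target threshold (e.g. 120 for onset-to-needle).
#' @return Minutes saved (>= 0).
#' @examples
#' minutes_saved(153, 120) # 34
#' minutes_saved(96, 120)  # 0, target already met
#' @export
minutes_saved <- function(baseline_minutes, threshold_minutes) {
  check_number(baseline_minutes, "baseline_minutes", 0, Inf, strict_lower = TRUE)
  check_number(threshold_minutes, "threshold_minutes", 0, Inf, strict_lower = TRUE)
  max(0, baseline_minutes - (threshold_minutes - 1))
}

#' Apply a time-to-treatment effect to an arm's outcome distribution
#'
#' Earlier treatment raises the mRS 0-2 proportion linearly
#' (`ard_per_minute` per minute saved) and lowers 90-day mortality through
#' the per-hour odds ratio: the odds of death are divided by
#' `OR^(minutes/60)` (or the probability itself under the `"risk"` rule).
#' mRS 3-5 takes the residual, so with OR = 1 the whole mRS 0-2 gain is
#' drawn from mRS 3-5.
#'
#' @param arm_dist the arm's baseline [mrs_distribution()].
#' @param saved minutes of earlier treatment (>= 0).
#' @param effects an [acute_effect_params()].
#' @param use_otp_override use the country's onset-to-puncture OR override
#'   (if set) instead of the generic mortality OR; set by the engine for the
#'   onset-to-puncture target.
#' @return The shifted [mrs_distribution()].
#' @export
apply_time_effect <- function(arm_dist, saved, effects,
                              use_otp_override = FALSE) {
  arm_dist <- as_mrs_distribution(arm_dist)
  saved <- check_number(saved, "saved", 0, Inf)
  stopifnot(inherits(effects, "acute_effect_params"))
  or <- if (use_otp_override && !is.null(effects$otp_or_override)) {
    effects$otp_or_override
  } else {
    effects$mortality_or_per_hour
  }
  p02 <- arm_dist[["p_mrs02"]]
  p6 <- arm_dist[["p_mrs6"]]

  p02_new <- p02 + effects$ard_per_minute * saved
  scale <- or^(saved / 60)
  p6_new <- if (effects$mortality_rule == "odds") {
    if (p6 >= 1) stopf("cannot rescale odds of a certain death probability")
    odds <- p6 / (1 - p6)
    odds_new <- odds / scale
    odds_new / (1 + odds_new)
  } else {
    p6 / scale
  }
  p35_new <- 1 - p02_new - p6_new
  if (p02_new > 1 + 1e-12 || p35_new < -1e-12) {
    stopf("time-to-treatment effect exceeds feasible range (p_mrs02' = %.4g, p_mrs35' = %.4g)",
          p02_new, p35_new)
  }
  mrs_distribution(min(p02_new, 1), max(p35_new, 0), p6_new)
}
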