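# Reading and writing country configuration files.
#
# Dialect: one YAML file per country holding the scalar/nested parameters,
# plus two sibling tab-delimited tables referenced from it -- the life table
# (age, qx) and the acute 90-day cost table (arm, band, cost). Rates carry an
# explicit unit tag ('fraction' or 'percent') so a file printing 17.5 cannot
# be silently misread as a fraction.

#' Load a country configuration
#'
#' Reads a YAML country file plus its referenced life-table and acute-cost
#' tables, applies the declared rate unit, and validates every type
#' invariant. Validation failures name the offending field.
#'
#' @param path path to the YAML country file.
#' @return A validated [country_config()].
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  dir <- dirname(path)

  prof_raw <- need_field(raw, "profile", "config")
  unit <- prof_raw$rates_unit %||% "fraction"
  if (!unit %in% c("fraction", "percent")) {
    stopf("profile.rates_unit must be 'fraction' or 'percent' (got '%s')", unit)
  }
  scale <- if (unit == "percent") 1 / 100 else 1
  profile <- treatment_profile(
    ivt_rate = need_field(prof_raw, "ivt_rate", "profile") * scale,
    evt_rate = need_field(prof_raw, "evt_rate", "profile") * scale,
    otn_minutes = need_field(prof_raw, "otn_minutes", "profile"),
    otp_minutes = need_field(prof_raw, "otp_minutes", "profile"))

  out_raw <- need_field(raw, "outcomes", "config")
  outcomes <- outcome_table(
    standard = mrs_from_raw(need_field(out_raw, "standard", "outcomes"), "outcomes.standard"),
    ivt = mrs_from_raw(need_field(out_raw, "ivt", "outcomes"), "outcomes.ivt"),
    evt = mrs_from_raw(need_field(out_raw, "evt", "outcomes"), "outcomes.evt"))

  tr_raw <- need_field(raw, "transitions", "config")
  rec_raw <- need_field(tr_raw, "recurrence", "transitions")
  exit_raw <- need_field(tr_raw, "recurrent_exit", "transitions")
  transitions <- transition_params(
    p_excess_death_mrs02 = need_field(tr_raw, "p_excess_death_mrs02", "transitions"),
    p_excess_death_mrs35 = need_field(tr_raw, "p_excess_death_mrs35", "transitions"),
    recurrence = recurrence_schedule(
      p_year1 = need_field(rec_raw, "p_year1", "transitions.recurrence"),
      p_years2_5 = need_field(rec_raw, "p_years2_5", "transitions.recurrence"),
      p_years6_10 = need_field(rec_raw, "p_years6_10", "transitions.recurrence"),
      p_beyond10 = rec_raw$p_beyond10 %||% 0),
    recurrent_exit = c(
      p_mrs02 = need_field(exit_raw, "p_mrs02", "transitions.recurrent_exit"),
      p_mrs35 = need_field(exit_raw, "p_mrs35", "transitions.recurrent_exit"),
      p_death = need_field(exit_raw, "p_death", "transitions.recurrent_exit")))

  ut_raw <- need_field(raw, "utilities", "config")
  utilities <- utility_set(
    u_mrs02 = need_field(ut_raw, "u_mrs02", "utilities"),
    u_mrs35 = need_field(ut_raw, "u_mrs35", "utilities"),
    u_dead = ut_raw$u_dead %||% 0,
    u_recurrent_year = ut_raw$u_recurrent_year,
    u_general_population = ut_raw$u_general_population)

  cost_raw <- need_field(raw, "costs", "config")
  acute_file <- file.path(dir, need_field(cost_raw, "acute_cost_file", "costs"))
  if (!file.exists(acute_file)) stopf("acute cost table not found: %s", acute_file)
  acute_df <- read.table(acute_file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  for (col in c("arm", "band", "cost")) {
    if (!col %in% names(acute_df)) {
      stopf("missing column '%s' in acute cost table %s", col, acute_file)
    }
  }
  acute_m <- matrix(NA_real_, 3, 3,
                    dimnames = list(TREATMENT_ARMS, c("mrs02", "mrs35", "mrs6")))
  for (i in seq_len(nrow(acute_df))) {
    acute_m[acute_df$arm[i], acute_df$band[i]] <- acute_df$cost[i]
  }
  if (anyNA(acute_m)) stopf("acute cost table %s misses arm/band cells", acute_file)
  costs <- cost_set(
    acute_cost_by_arm_and_band = acute_m,
    annual_cost_mrs02 = need_field(cost_raw, "annual_cost_mrs02", "costs"),
    annual_cost_mrs35 = need_field(cost_raw, "annual_cost_mrs35", "costs"),
    recurrent_event_cost = need_field(cost_raw, "recurrent_event_cost", "costs"),
    currency_year = cost_raw$currency_year %||% 2023)

  lt_file <- file.path(dir, need_field(raw, "life_table_file", "config"))
  if (!file.exists(lt_file)) stopf("life table not found: %s", lt_file)
  lt_df <- read.table(lt_file, header = TRUE, sep = "\t")
  for (col in c("age", "qx")) {
    if (!col %in% names(lt_df)) {
      stopf("missing column '%s' in life table %s", col, lt_file)
    }
  }
  lt <- life_table(lt_df$age, lt_df$qx)

  ae_raw <- need_field(raw, "acute_effects", "config")
  acute_effects <- acute_effect_params(
    ard_per_minute = need_field(ae_raw, "ard_per_minute", "acute_effects"),
    mortality_or_per_hour = need_field(ae_raw, "mortality_or_per_hour",
                                       "acute_effects"),
    otp_or_override = ae_raw$otp_or_override,
    mortality_rule = ae_raw$mortality_rule %||% "odds")

  country_config(
    name = need_field(raw, "country", "config"),
    cohort_start_age = need_field(raw, "cohort_start_age", "config"),
    discount_rate = need_field(raw, "discount_rate", "config"),
    annual_incidence = need_field(raw, "annual_incidence", "config"),
    profile = profile, outcomes = outcomes, transitions = transitions,
    utilities = utilities, costs = costs, life_table = lt,
    acute_effects = acute_effects,
    synthetic_fields = unlist(raw$synthetic_fields) %||% character())
}

mrs_from_raw <- function(x, where) {
  mrs_distribution(need_field(x, "p_mrs02", where),
                   need_field(x, "p_mrs35", where),
                   need_field(x, "p_mrs6", where))
}

#' Save a country configuration
#'
#' Writes the YAML country file and its two sibling tables
#' (`<stem>_life_table.tsv`, `<stem>_acute_costs.tsv`). The emitted files
#' load back to a configuration equal to the input at full numeric
#' precision.
#'
#' @param config a [country_config()].
#' @param path destination YAML path.
#' @param overwrite overwrite existing files? Defaults to `FALSE`, in which
#'   case an existing destination is an error.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path, overwrite = FALSE) {
  stopifnot(inherits(config, "country_config"))
  dir <- dirname(path)
  stem <- sub("\\.[^.]*$", "", basename(path))
  lt_name <- paste0(stem, "_life_table.tsv")
  cost_name <- paste0(stem, "_acute_costs.tsv")
  targets <- c(path, file.path(dir, lt_name), file.path(dir, cost_name))
  if (!overwrite && any(file.exists(targets))) {
    stopf("refusing to overwrite existing file(s): %s; pass overwrite = TRUE",
          paste(targets[file.exists(targets)], collapse = ", "))
  }
  if (!dir.exists(dir)) stopf("destination directory does not exist: %s", dir)

  m <- config$costs$acute_cost_by_arm_and_band
  acute_df <- data.frame(arm = rep(rownames(m), times = ncol(m)),
                         band = rep(colnames(m), each = nrow(m)),
                         cost = as.vector(m))
  write.table(format_numeric_df(acute_df), file.path(dir, cost_name),
              sep = "\t", quote = FALSE, row.names = FALSE)
  lt_df <- data.frame(age = config$life_table$age, qx = config$life_table$qx)
  write.table(format_numeric_df(lt_df), file.path(dir, lt_name),
              sep = "\t", quote = FALSE, row.names = FALSE)

  doc <- list(
    country = config$name,
    cohort_start_age = config$cohort_start_age,
    discount_rate = config$discount_rate,
    annual_incidence = config$annual_incidence,
    profile = c(list(rates_unit = "fraction"),
                unclass(config$profile)),
    outcomes = lapply(unclass(config$outcomes), function(d) as.list(unclass(d))),
    acute_effects = drop_nulls(unclass(config$acute_effects)),
    transitions = list(
      p_excess_death_mrs02 = config$transitions$p_excess_death_mrs02,
      p_excess_death_mrs35 = config$transitions$p_excess_death_mrs35,
      recurrence = unclass(config$transitions$recurrence),
      recurrent_exit = as.list(config$transitions$recurrent_exit)),
    utilities = unclass(config$utilities),
    costs = list(
      currency_year = config$costs$currency_year,
      annual_cost_mrs02 = config$costs$annual_cost_mrs02,
      annual_cost_mrs35 = config$costs$annual_cost_mrs35,
      recurrent_event_cost = config$costs$recurrent_event_cost,
      acute_cost_file = cost_name),
    life_table_file = lt_name)
  if (length(config$synthetic_fields)) {
    doc$synthetic_fields <- as.list(config$synthetic_fields)
  }
  writeLines(yaml::as.yaml(doc, precision = 15L), path)
  invisible(path)
}

drop_nulls <- function(x) x[!vapply(x, is.null, logical(1))]

# Full-precision text rendering for the sibling TSV tables.
format_numeric_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) format(v, digits = 17),
                         character(1))
    }
  }
  df
}

#' Convert a cost to target-year euros
#'
#' Applies a currency conversion and a healthcare inflation factor:
#' `amount * fx_rate * inflation_factor`.
#'
#' @param amount cost in the source currency and year.
#' @param fx_rate euros per source-currency unit (e.g. 0.86 EUR per USD).
#' @param inflation_factor cumulative healthcare price-index factor from the
#'   source year to the target year.
#' @return Cost in target-year euros.
#' @examples
#' convert_costs(100, 0.86, 1) # 100 USD -> 86 EUR
#' @export
convert_costs <- function(amount, fx_rate, inflation_factor) {
  check_number(amount, "amount")
  check_number(fx_rate, "fx_rate", 0, Inf, strict_lower = TRUE)
  check_number(inflation_factor, "inflation_factor", 0, Inf,
               strict_lower = TRUE)
  amount * fx_rate * inflation_factor
}
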