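# Reporting: the country-by-target result matrix, delimited/structured-text
# rendering with fixed display precision (2 dp for percentage points and
# euros, 4 dp for QALYs), and a run manifest. All arithmetic happens in the
# model; rendering only rounds.

#' Run every target against every country
#'
#' @param configs list of [country_config()] objects.
#' @param targets list of [scenario_spec()] objects; defaults to the six
#'   standard targets.
#' @param reset_clock recurrence-clock convention, see [run_cohort()].
#' @return A data frame of class `target_matrix`, one row per
#'   (target, country): incremental outcomes, ICER status, mRS changes and
#'   scope. Cells whose absolute target is already met at baseline carry
#'   `met_already = TRUE` and `NA` outcomes; per-cell failures are recorded
#'   in `error` and do not stop the run.
#' @export
run_matrix <- function(configs, targets = lapply(1:6, scenario_spec),
                       reset_clock = FALSE) {
  if (!length(configs) || !length(targets)) {
    stopf("nothing to run: need at least one config and one target")
  }
  rows <- list()
  for (spec in targets) {
    for (config in configs) {
      row <- tryCatch({
        res <- run_comparison(config, spec, reset_clock = reset_clock)
        if (res$met_already) {
          data.frame(country = config$name, target = spec$target_id,
                     met_already = TRUE, inc_cost = NA_real_,
                     inc_qalys = NA_real_, icer = NA_real_,
                     icer_status = NA_character_,
                     mrs02_change_pp = NA_real_, mrs35_change_pp = NA_real_,
                     scope = NA_character_, error = NA_character_,
                     stringsAsFactors = FALSE)
        } else {
          data.frame(country = config$name, target = spec$target_id,
                     met_already = FALSE, inc_cost = res$econ$inc_cost,
                     inc_qalys = res$econ$inc_qalys,
                     icer = res$econ$icer$value,
                     icer_status = res$econ$icer$status,
                     mrs02_change_pp = res$econ$mrs02_change_pp,
                     mrs35_change_pp = res$econ$mrs35_change_pp,
                     scope = res$econ$scope, error = NA_character_,
                     stringsAsFactors = FALSE)
        }
      }, error = function(e) {
        data.frame(country = config$name, target = spec$target_id,
                   met_already = NA, inc_cost = NA_real_,
                   inc_qalys = NA_real_, icer = NA_real_,
                   icer_status = NA_character_, mrs02_change_pp = NA_real_,
                   mrs35_change_pp = NA_real_, scope = NA_character_,
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("target_matrix", "data.frame")
  out
}

fmt_cell <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

render_rows <- function(results) {
  icer_cell <- character(nrow(results))
  for (i in seq_len(nrow(results))) {
    st <- results$icer_status[i]
    icer_cell[i] <- if (is.na(st)) "NA"
    else if (st == "icer") formatC(results$icer[i], format = "f", digits = 2)
    else if (st == "dominant") "Dominant"
    else if (st == "dominated") "Dominated"
    else if (st == "no_difference") "No difference"
    else "Undefined"
  }
  data.frame(country = results$country, target = results$target,
             inc_cost_eur = fmt_cell(results$inc_cost, 2),
             inc_qalys = fmt_cell(results$inc_qalys, 4),
             icer = icer_cell,
             mrs02_change_pp = fmt_cell(results$mrs02_change_pp, 2),
             mrs35_change_pp = fmt_cell(results$mrs35_change_pp, 2),
             scope = ifelse(is.na(results$scope), "NA", results$scope),
             stringsAsFactors = FALSE)
}

#' Render a result matrix to a report file
#'
#' `"delimited"` writes a tab-separated table; `"structured-text"` writes a
#' fixed-width per-target layout. Numeric display follows the package
#' convention (percentage points and euros to 2 decimals, QALYs to 4;
#' dominance rendered literally as `"Dominant"`). Rendering identical
#' results yields byte-identical files; a JSON manifest is written next to
#' the report.
#'
#' @param results a [run_matrix()] result.
#' @param format `"delimited"` or `"structured-text"`.
#' @param path destination file.
#' @param manifest optional [run_manifest()]; written to
#'   `<path>.manifest.json` when supplied.
#' @return `path`, invisibly.
#' @export
render_report <- function(results, format = c("delimited", "structured-text"),
                          path, manifest = NULL) {
  stopifnot(inherits(results, "target_matrix"))
  if (!is.character(format) || !format[1] %in% c("delimited", "structured-text")) {
    stopf("unknown report format '%s'", format[1])
  }
  format <- format[1]
  rendered <- render_rows(results)
  if (format == "delimited") {
    lines <- c(paste(names(rendered), collapse = "\t"),
               apply(rendered, 1L, paste, collapse = "\t"))
  } else {
    lines <- character()
    for (tid in sort(unique(rendered$target))) {
      sub <- rendered[rendered$target == tid, , drop = FALSE]
      lines <- c(lines,
                 sprintf("Target %d -- %s", tid, target_label(tid)),
                 sprintf("  %-16s %14s %10s %14s %10s %10s",
                         "country", "inc cost (EUR)", "inc QALYs", "ICER",
                         "d mRS 0-2", "d mRS 3-5"),
                 sprintf("  %-16s %14s %10s %14s %10s %10s", sub$country,
                         sub$inc_cost_eur, sub$inc_qalys, sub$icer,
                         sub$mrs02_change_pp, sub$mrs35_change_pp),
                 "")
    }
  }
  writeLines(lines, path)
  if (!is.null(manifest)) {
    jsonlite::write_json(unclass(manifest), paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Capture the configuration of a run
#'
#' @param configs list of [country_config()] objects.
#' @param targets list of [scenario_spec()] objects.
#' @param seed seed used for any stochastic component (or `NA`).
#' @return A list of class `run_manifest` with the tool version, per-config
#'   hashes, the scenario list, seed and timestamp.
#' @export
run_manifest <- function(configs, targets, seed = NA) {
  structure(list(
    tool = "strokecea",
    version = as.character(utils::packageVersion("strokecea")),
    config_hashes = lapply(stats::setNames(configs, vapply(configs, `[[`,
                                                           "", "name")),
                           rlang::hash),
    targets = vapply(targets, `[[`, integer(1), "target_id"),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}
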