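format_gbp <- function(x, prefix = "£") {
  ifelse(is.na(x), "—",
         paste0(ifelse(x < 0, "−", ""), prefix,
                format(abs(round(x)), big.mark = ",", trim = TRUE,
                       scientific = FALSE)))
}

#' Render a scenario-suite result as a publication-style table
#'
#' Formats the output of [run_scenario_suite()] the way the published
#' tables present it: costs rounded to the pound with thousands
#' separators, per-person QALYs to 3 decimals, net QALYs to 4 decimals,
#' ICERs to the pound computed from unrounded values, and dominance
#' rendered as `"Intervention dominates"`.
#'
#' @param suite A [run_scenario_suite()] result (possibly empty).
#' @param file Optional path; when given the formatted table is also
#'   written as CSV.
#' @return A character `data.frame` with the formatted columns.
#' @export
#' @examples
#' p <- base_case_parameters()
#' render_cea_table(run_scenario_suite(p, effects = c(0.025, 0.10)))
render_cea_table <- function(suite, file = NULL) {
  if (!nrow(suite)) {
    out <- data.frame()
    if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
    return(out)
  }
  icer_txt <- ifelse(
    suite$verdict == "dominant", "Intervention dominates",
    ifelse(suite$verdict == "dominated", "Intervention dominated",
           ifelse(is.na(suite$icer), "—", format_gbp(suite$icer))))
  out <- data.frame(
    `Sample-level effect` = ifelse(
      suite$effect == 0, "0% (no intervention)",
      paste0(formatC(100 * suite$effect, format = "g"), "%")),
    `Horizon (years)` = suite$horizon_years,
    `Intervention cost` = ifelse(is.na(suite$intervention_cost), "—",
                                 format_gbp(suite$intervention_cost)),
    `Cost per person` = format_gbp(suite$cost_per_person),
    `Net cost` = format_gbp(suite$net_cost),
    `QALYs per person` = sprintf("%.3f", suite$qalys_per_person),
    `Net QALYs` = ifelse(is.na(suite$net_qalys), "—",
                         sprintf("%.4f", suite$net_qalys)),
    ICER = icer_txt,
    check.names = FALSE)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Run manifest for reproducibility
#'
#' A small record of what produced a results file: the resolved
#' parameter hash, the command description, seeds, timestamp, and
#' package version.
#'
#' @param params A [model_parameters()] bundle.
#' @param command Free-text description of the run.
#' @param seed Seed(s) used, if any.
#' @return A list of class `"run_manifest"`.
#' @export
run_manifest <- function(params, command = "", seed = NULL) {
  structure(
    list(parameter_hash = rlang::hash(unclass(params)),
         command = command,
         seed = seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         package_version = as.character(utils::packageVersion("depcem"))),
    class = "run_manifest"
  )
}

#' Write suite results with their manifest
#'
#' Writes the raw (unrounded) scenario results as CSV together with a
#' `<path>.manifest.yaml` sidecar referencing the manifest that produced
#' them.
#'
#' @param suite A [run_scenario_suite()] result.
#' @param path Output CSV path.
#' @param manifest A [run_manifest()].
#' @return `path`, invisibly.
#' @export
write_results <- function(suite, path, manifest) {
  utils::write.csv(suite, path, row.names = FALSE)
  yaml::write_yaml(unclass(manifest), paste0(path, ".manifest.yaml"))
  invisible(path)
}
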