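#' Write and read cost-savings reports
#'
#' Three formats, chosen by `format` (default: from the file extension,
#' falling back to text):
#'
#' * `json` — every figure in exact cents alongside display dollars, plus
#'   counts, unit costs, ROI and any scenario results; lossless, and
#'   [read_report()] reconstructs an identical report object.
#' * `csv` — one row per savings component (and per scenario component),
#'   with cents, dollars and percent-of-gross columns.
#' * `text` — the human-readable table, including the percentage
#'   breakdown of gross savings by component (suppressed for an all-zero
#'   report).
#'
#' @param report A `cvm_cost_report`.
#' @param path Output file path.
#' @param format `"json"`, `"csv"` or `"text"`.
#' @param scenarios Optional list of `cvm_scenario_result` objects.
#' @return `write_report()` the path, invisibly; `read_report()` a list
#'   with elements `report` and `scenarios`.
#' @examples
#' r <- compute_cost_report(fixture_ledger_2020(), default_config())
#' p <- tempfile(fileext = ".json")
#' write_report(r, p)
#' identical(read_report(p)$report, r)
#' @export
write_report <- function(report, path, format = NULL, scenarios = NULL) {
  stopifnot(inherits(report, "cvm_cost_report"))
  if (inherits(scenarios, "cvm_scenario_result")) scenarios <- list(scenarios)
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               json = "json", csv = "csv", "text")
  format <- rlang::arg_match(format, c("json", "csv", "text"))
  switch(format,
    json = write_report_json(report, scenarios, path),
    csv = write_report_csv(report, scenarios, path),
    text = write_report_text(report, scenarios, path)
  )
  invisible(path)
}

report_cents_fields <- c(
  "per_call_time_cost_cents", "per_change_ppe_cost_cents",
  "equipment_cost_per_day_cents", "time_savings_cents", "ppe_savings_cents",
  "gross_savings_cents", "equipment_cost_cents", "net_savings_cents"
)

write_report_json <- function(report, scenarios, path) {
  cents_list <- report[report_cents_fields]
  doc <- list(
    n_calls_averted = report$n_calls_averted,
    monitored_patient_days = report$monitored_patient_days,
    cents = cents_list,
    dollars = purrr::map(cents_list, dollars),
    roi = report$roi,
    roi_sig_figs = report$roi_sig_figs,
    equipment_cost_overridden = report$equipment_cost_overridden,
    scenarios = purrr::map(scenarios %||% list(), function(s) {
      list(
        label = s$scenario$label,
        added_hours = s$scenario$added_hours,
        hourly_rate = s$scenario$hourly_rate,
        staffing_cost_cents = s$staffing_cost_cents,
        staffing_cost = dollars(s$staffing_cost_cents),
        adjusted_net_savings_cents = s$adjusted_net_savings_cents,
        adjusted_net_savings = dollars(s$adjusted_net_savings_cents),
        adjusted_program_cost_cents = s$adjusted_program_cost_cents,
        adjusted_roi = s$adjusted_roi
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  # the engine holds every numeric as double (cent values in doubles)
  report <- structure(
    c(
      list(n_calls_averted = as.numeric(doc$n_calls_averted),
           monitored_patient_days = as.numeric(doc$monitored_patient_days)),
      purrr::map(doc$cents[report_cents_fields], as.numeric),
      list(roi = as.numeric(doc$roi %||% NA_real_),
           roi_sig_figs = as.numeric(doc$roi_sig_figs),
           equipment_cost_overridden = doc$equipment_cost_overridden)
    ),
    class = "cvm_cost_report"
  )
  list(
    report = report,
    scenarios = purrr::map(doc$scenarios %||% list(), function(s) {
      structure(
        list(
          scenario = staffing_scenario(s$label, hourly_rate = as.numeric(s$hourly_rate),
                                       added_hours = as.numeric(s$added_hours)),
          staffing_cost_cents = as.numeric(s$staffing_cost_cents),
          adjusted_net_savings_cents = as.numeric(s$adjusted_net_savings_cents),
          adjusted_program_cost_cents = as.numeric(s$adjusted_program_cost_cents),
          adjusted_roi = as.numeric(s$adjusted_roi),
          base = report
        ),
        class = "cvm_scenario_result"
      )
    })
  )
}

write_report_csv <- function(report, scenarios, path) {
  base <- dplyr::mutate(report_components(report), scenario = NA_character_,
                        .before = 1)
  scen <- purrr::map_dfr(scenarios %||% list(), function(s) {
    tibble::tibble(
      scenario = s$scenario$label,
      component = c("staffing_cost", "adjusted_net_savings"),
      cents = c(s$staffing_cost_cents, s$adjusted_net_savings_cents),
      dollars = dollars(cents),
      pct_of_gross = NA_real_
    )
  })
  readr::write_csv(dplyr::bind_rows(base, scen), path, progress = FALSE)
}

write_report_text <- function(report, scenarios, path) {
  out <- c(
    utils::capture.output(print(report)),
    unlist(purrr::map(scenarios %||% list(),
                      ~ utils::capture.output(print(.x))))
  )
  readr::write_lines(out, path)
}
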