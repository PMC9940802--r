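#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cost report into its component breakdown
#'
#' One row per savings component (staff time, PPE, gross, equipment,
#' net), with exact cents, display dollars, and percent of gross savings.
#'
#' @param x A `cvm_cost_report`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `cents`, `dollars`,
#'   `pct_of_gross`.
#' @examples
#' tidy(compute_cost_report(fixture_ledger_2020(), default_config()))
#' @export
tidy.cvm_cost_report <- function(x, ...) {
  report_components(x)
}

#' @rdname tidy.cvm_cost_report
#' @export
glance.cvm_cost_report <- function(x, ...) {
  tibble::tibble(
    n_calls_averted = x$n_calls_averted,
    monitored_patient_days = x$monitored_patient_days,
    per_call_time_cost = dollars(x$per_call_time_cost_cents),
    per_change_ppe_cost = dollars(x$per_change_ppe_cost_cents),
    equipment_cost_per_day = dollars(x$equipment_cost_per_day_cents),
    time_savings = dollars(x$time_savings_cents),
    ppe_savings = dollars(x$ppe_savings_cents),
    gross_savings = dollars(x$gross_savings_cents),
    equipment_cost = dollars(x$equipment_cost_cents),
    net_savings = dollars(x$net_savings_cents),
    roi = x$roi
  )
}

#' Tidy a staffing-scenario result
#'
#' @param x A `cvm_scenario_result`.
#' @param ... Unused.
#' @return `tidy()` a component tibble; `glance()` a one-row summary.
#' @export
tidy.cvm_scenario_result <- function(x, ...) {
  tibble::tibble(
    component = c("staffing_cost", "adjusted_program_cost", "adjusted_net_savings"),
    cents = c(x$staffing_cost_cents, x$adjusted_program_cost_cents,
              x$adjusted_net_savings_cents),
    dollars = dollars(cents)
  )
}

#' @rdname tidy.cvm_scenario_result
#' @export
glance.cvm_scenario_result <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario$label,
    added_hours = x$scenario$added_hours,
    hourly_rate = x$scenario$hourly_rate,
    staffing_cost = dollars(x$staffing_cost_cents),
    adjusted_net_savings = dollars(x$adjusted_net_savings_cents),
    adjusted_roi = x$adjusted_roi,
    base_net_savings = dollars(x$base$net_savings_cents),
    base_roi = x$base$roi
  )
}
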