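#' Adjust a cost report for an added-staffing scenario
#'
#' Added monitor staffing is a semi-fixed capacity cost: it reduces net
#' savings dollar-for-dollar and enters the ROI denominator alongside the
#' equipment program cost (it is program cost, not a reduction of the
#' gross savings line items):
#'
#' * `adjusted_net = net - staffing_cost` (exact in cents)
#' * `adjusted_roi = adjusted_net / (equipment_cost + staffing_cost)`
#'
#' The published scenario (0.5 FTE around the clock, $15/h, 3,240 h =
#' $48,600) reduces the 2020 program's net savings to $351,278 and its
#' ROI to 5.16.
#'
#' @param report A [compute_cost_report()] result.
#' @param scenario A [staffing_scenario()].
#' @return A `cvm_scenario_result` with the scenario, its cost, and the
#'   adjusted net savings and ROI. [tidy()]/[glance()] methods apply.
#' @examples
#' fixture_ledger_2020() |>
#'   compute_cost_report(default_config()) |>
#'   apply_staffing_scenario(default_scenarios()[[1]])
#' @export
apply_staffing_scenario <- function(report, scenario) {
  stopifnot(inherits(report, "cvm_cost_report"),
            inherits(scenario, "cvm_staffing_scenario"))
  staffing <- staffing_cost_cents(scenario)
  adjusted_net <- report$net_savings_cents - staffing
  denom <- report$equipment_cost_cents + staffing
  if (denom <= 0) {
    abort_invalid("ROI undefined: adjusted program cost is zero", field = "scenario")
  }
  structure(
    list(
      scenario = scenario,
      staffing_cost_cents = staffing,
      adjusted_net_savings_cents = adjusted_net,
      adjusted_program_cost_cents = denom,
      adjusted_roi = signif(adjusted_net / denom, report$roi_sig_figs),
      base = report
    ),
    class = "cvm_scenario_result"
  )
}

#' @export
print.cvm_scenario_result <- function(x, ...) {
  cat(sprintf("Scenario `%s`\n", x$scenario$label))
  cat(sprintf("  staffing cost      %14s (%s h @ %s/h)\n",
              fmt_dollars(x$staffing_cost_cents),
              format(x$scenario$added_hours, big.mark = ","),
              fmt_dollars(cents(x$scenario$hourly_rate))))
  cat(sprintf("  adjusted net       %14s (base %s)\n",
              fmt_dollars(x$adjusted_net_savings_cents),
              fmt_dollars(x$base$net_savings_cents)))
  cat(sprintf("  adjusted ROI       %14s (base %s)\n",
              format(x$adjusted_roi), format(x$base$roi)))
  invisible(x)
}

#' One-way parameter sweep
#'
#' Recomputes the full costing pipeline once per candidate value of a
#' single configuration leaf (dotted path, see [set_config_value()]),
#' holding every other parameter at its configured value. A deterministic
#' generalisation of the published single staffing scenario; the input
#' config is never modified.
#'
#' @param totals A ledger or ledger-totals tibble.
#' @param config A [cost_config()].
#' @param parameter_path Dotted path to a numeric leaf, e.g.
#'   `"equipment.cleaning_cost_per_day"` or `"ppe.masks.N95.unit_cost"`.
#' @param values Numeric vector of candidate values.
#' @return A `cvm_sweep` tibble: one row per value with the savings
#'   decomposition in dollars and the ROI.
#' @examples
#' fixture_ledger_2020() |>
#'   one_way_sweep(default_config(), "equipment.cleaning_cost_per_day",
#'                 c(0, 5, 10, 20))
#' @export
one_way_sweep <- function(totals, config = default_config(), parameter_path, values) {
  stopifnot(inherits(config, "cvm_config"))
  if (length(values) == 0) {
    abort_invalid("`values` must be non-empty", field = "values")
  }
  if ("date" %in% names(totals)) totals <- aggregate_ledger(totals)
  rows <- purrr::map(values, function(v) {
    report <- compute_cost_report(totals, set_config_value(config, parameter_path, v))
    tibble::tibble(
      parameter = parameter_path,
      value = v,
      time_savings = dollars(report$time_savings_cents),
      ppe_savings = dollars(report$ppe_savings_cents),
      gross_savings = dollars(report$gross_savings_cents),
      equipment_cost = dollars(report$equipment_cost_cents),
      net_savings = dollars(report$net_savings_cents),
      roi = report$roi
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cvm_sweep", class(out))
  out
}

#' Breakeven averted-call rate
#'
#' The averted-calls-per-monitored-patient-day rate at which the program
#' exactly pays for itself: the per-day device cost divided by the
#' per-call saving (staff time plus PPE). Because savings are linear in
#' call count at fixed per-event unit costs, the closed form is exact —
#' below this rate a monitored day costs more than it saves. Defaults
#' give 14.11 / (12.19 + 9.78) = 0.642 calls per monitored day.
#'
#' @param config A [cost_config()].
#' @return The breakeven rate (calls per monitored patient day).
#' @examples
#' breakeven_calls_per_monitored_day(default_config())
#' @export
breakeven_calls_per_monitored_day <- function(config = default_config()) {
  stopifnot(inherits(config, "cvm_config"))
  per_call <- per_call_time_cost_cents(config$timing, config$wage) +
    kit_cost_cents(config$ppe)
  if (per_call <= 0) {
    abort_invalid("no breakeven: per-call saving (time + PPE) is zero",
                  field = "config")
  }
  equipment_per_day_cents(config$equipment) / per_call
}
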