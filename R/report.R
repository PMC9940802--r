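#' Compute the full cost-savings report
#'
#' The core TDABC pipeline. Each averted in-person interaction saves one
#' donning/doffing cycle (staff time at the effective hourly rate) and one
#' PPE change (catalogue kit cost); each monitored patient day incurs the
#' per-day device cost. Per-event unit costs are rounded half-up to cents
#' first, then multiplied by the integer counts, so every identity below
#' holds exactly in cents:
#'
#' * `gross = time_savings + ppe_savings`
#' * `net = gross - equipment_cost`
#' * `roi = net / equipment_cost` (undefined at zero program cost)
#'
#' `data` may be a ledger tibble (aggregated over its full date range) or
#' a totals row from [aggregate_ledger()]. If
#' `config$options$equipment_total_override` is set, that dollar total
#' replaces the computed `monitored days x per-day cost` program cost.
#'
#' @param data A ledger or ledger-totals tibble.
#' @param config A [cost_config()].
#' @return A `cvm_cost_report`: counts, per-event unit costs and all
#'   savings components in cents, plus `roi`. Use [tidy()] for the
#'   component breakdown, [glance()] for a one-row dollar summary,
#'   [autoplot()] for the savings figure.
#' @examples
#' fixture_ledger_2020() |> compute_cost_report(default_config())
#' @export
compute_cost_report <- function(data, config = default_config()) {
  stopifnot(inherits(config, "cvm_config"))
  totals <- if ("date" %in% names(data)) aggregate_ledger(data) else data
  needed <- c("total_calls_averted", "total_monitored_patient_days")
  if (!all(needed %in% names(totals)) || nrow(totals) != 1) {
    abort_invalid("`data` must be a ledger or a one-row totals tibble", field = "data")
  }
  n_calls <- check_number(totals$total_calls_averted, "total_calls_averted",
                          min = 0, integer = TRUE)
  n_days <- check_number(totals$total_monitored_patient_days, "total_monitored_patient_days",
                         min = 0, integer = TRUE)

  pc_time <- per_call_time_cost_cents(config$timing, config$wage)
  pc_ppe <- kit_cost_cents(config$ppe)
  eq_day <- equipment_per_day_cents(config$equipment)

  time_savings <- n_calls * pc_time
  ppe_savings <- n_calls * pc_ppe
  gross <- time_savings + ppe_savings
  override <- config$options$equipment_total_override
  equipment_cost <- if (is.null(override)) n_days * eq_day else cents(override)
  net <- gross - equipment_cost
  sf <- config$options$roi_sig_figs
  roi_value <- if (equipment_cost > 0) signif(net / equipment_cost, sf) else NA_real_

  structure(
    list(
      n_calls_averted = n_calls,
      monitored_patient_days = n_days,
      per_call_time_cost_cents = pc_time,
      per_change_ppe_cost_cents = pc_ppe,
      equipment_cost_per_day_cents = eq_day,
      time_savings_cents = time_savings,
      ppe_savings_cents = ppe_savings,
      gross_savings_cents = gross,
      equipment_cost_cents = equipment_cost,
      net_savings_cents = net,
      roi = roi_value,
      roi_sig_figs = sf,
      equipment_cost_overridden = !is.null(override)
    ),
    class = "cvm_cost_report"
  )
}

#' Return on investment
#'
#' Net savings divided by program cost, reported to `sig_figs`
#' significant figures (3 reproduces published conventions: 20.6 base
#' case, 5.16 under added staffing). A non-positive program cost has no
#' defined ROI and raises an error rather than returning an infinity.
#'
#' @param net Net savings in dollars.
#' @param program_cost Program cost in dollars (> 0).
#' @param sig_figs Significant figures for the reported ratio.
#' @return The ROI ratio.
#' @examples
#' roi(399878, 19441)  # 20.6
#' @export
roi <- function(net, program_cost, sig_figs = 3) {
  net <- check_number(net, "net")
  program_cost <- check_number(program_cost, "program_cost")
  if (program_cost <= 0) {
    abort_invalid("ROI undefined: `program_cost` must be > 0", field = "program_cost")
  }
  signif(net / program_cost, check_number(sig_figs, "sig_figs", min = 1, integer = TRUE))
}

report_components <- function(report) {
  gross <- report$gross_savings_cents
  tibble::tibble(
    component = c("time_savings", "ppe_savings", "gross_savings",
                  "equipment_cost", "net_savings"),
    cents = c(report$time_savings_cents, report$ppe_savings_cents, gross,
              report$equipment_cost_cents, report$net_savings_cents),
    dollars = dollars(c(report$time_savings_cents, report$ppe_savings_cents, gross,
                        report$equipment_cost_cents, report$net_savings_cents)),
    pct_of_gross = if (gross > 0) {
      100 * c(report$time_savings_cents, report$ppe_savings_cents, gross,
              report$equipment_cost_cents, report$net_savings_cents) / gross
    } else {
      NA_real_
    }
  )
}

#' @export
print.cvm_cost_report <- function(x, ...) {
  cat("Continuous virtual monitoring cost-savings report\n")
  cat(sprintf("  %s averted calls over %s monitored patient days\n",
              format(x$n_calls_averted, big.mark = ","),
              format(x$monitored_patient_days, big.mark = ",")))
  cat(sprintf("  unit costs: %s/call staff time, %s/PPE change, %s/monitored day\n",
              fmt_dollars(x$per_call_time_cost_cents),
              fmt_dollars(x$per_change_ppe_cost_cents),
              fmt_dollars(x$equipment_cost_per_day_cents)))
  comp <- report_components(x)
  labels <- c(time_savings = "Staff-time savings", ppe_savings = "PPE savings",
              gross_savings = "Gross savings", equipment_cost = "Program equipment cost",
              net_savings = "Net savings")
  for (i in seq_len(nrow(comp))) {
    pct <- if (!is.na(comp$pct_of_gross[i]) &&
               comp$component[i] %in% c("time_savings", "ppe_savings")) {
      sprintf("  (%s%% of gross)", fmt_ratio1(comp$pct_of_gross[i]))
    } else ""
    cat(sprintf("  %-24s %14s%s\n", labels[[comp$component[i]]],
                fmt_dollars(comp$cents[i]), pct))
  }
  if (x$equipment_cost_overridden) {
    cat("  (equipment cost from configured program total, not days x rate)\n")
  }
  cat(sprintf("  ROI: %s\n",
              if (is.na(x$roi)) "undefined (zero program cost)" else format(x$roi)))
  invisible(x)
}
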