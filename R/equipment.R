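#' CVM device cost profile
#'
#' One monitoring station (interactive telehealth monitor plus portable
#' cart) serves one isolated patient at a time, so device cost accrues per
#' monitored patient day. The purchase price is amortized linearly over
#' the service life, rounded half-up to cents per day, and daily cleaning
#' is added on top. Defaults: $4,500 purchase over 3 years at 365
#' days/year ($4.11/day) plus $10.00/day cleaning, $14.11 per monitored
#' day in total.
#'
#' @param purchase_cost Device purchase price in dollars (>= 0).
#' @param amortization_years Service life in years (> 0).
#' @param days_per_year Amortization days per year; 365 by default (no
#'   leap-year adjustment).
#' @param cleaning_cost_per_day Daily cleaning cost in dollars (>= 0).
#' @return `equipment_profile()` returns a `cvm_equipment_profile`;
#'   `equipment_cost_per_day()` the total daily cost in dollars.
#' @examples
#' equipment_cost_per_day(equipment_profile())  # 14.11
#' @export
equipment_profile <- function(purchase_cost = 4500,
                              amortization_years = 3,
                              days_per_year = 365,
                              cleaning_cost_per_day = 10) {
  structure(
    list(
      purchase_cost = check_number(purchase_cost, "purchase_cost", min = 0),
      amortization_years = check_number(amortization_years, "amortization_years",
                                        min = 0, exclusive_min = TRUE),
      days_per_year = check_number(days_per_year, "days_per_year",
                                   min = 0, exclusive_min = TRUE, integer = TRUE),
      cleaning_cost_per_day = check_number(cleaning_cost_per_day, "cleaning_cost_per_day",
                                           min = 0)
    ),
    class = "cvm_equipment_profile"
  )
}

amortized_cents_per_day <- function(equip) {
  round_half_up(cents(equip$purchase_cost) / equip$amortization_years / equip$days_per_year)
}

equipment_per_day_cents <- function(equip) {
  amortized_cents_per_day(equip) + cents(equip$cleaning_cost_per_day)
}

#' @rdname equipment_profile
#' @param equip An [equipment_profile()].
#' @export
equipment_cost_per_day <- function(equip) {
  stopifnot(inherits(equip, "cvm_equipment_profile"))
  dollars(equipment_per_day_cents(equip))
}

#' @export
print.cvm_equipment_profile <- function(x, ...) {
  cat("<equipment profile>\n")
  cat(sprintf("  purchase  %s over %g yr x %d d/yr -> %s/day\n",
              fmt_dollars(cents(x$purchase_cost)), x$amortization_years,
              as.integer(x$days_per_year), fmt_dollars(amortized_cents_per_day(x))))
  cat(sprintf("  cleaning  %s/day -> total %s/day\n",
              fmt_dollars(cents(x$cleaning_cost_per_day)),
              fmt_dollars(equipment_per_day_cents(x))))
  invisible(x)
}

#' Added-staffing scenario
#'
#' A semi-fixed staffing addition treated as program cost in sensitivity
#' analysis: extra monitor-staff hours at a given wage. Hours may be given
#' directly or derived as `fte_added * hours_per_day * n_days`. The
#' published scenario adds 0.5 FTE around the clock at $15/h for 3,240 h
#' ($48,600).
#'
#' @param label Scenario name.
#' @param hourly_rate Added-staff wage in dollars per hour (>= 0).
#' @param added_hours Total added hours (>= 0); if `NULL`, derived from
#'   the three fields below.
#' @param fte_added Full-time equivalents added (>= 0).
#' @param hours_per_day Coverage hours per day.
#' @param n_days Days of added coverage.
#' @return `staffing_scenario()` returns a `cvm_staffing_scenario`;
#'   `staffing_scenario_cost()` its total cost in dollars.
#' @examples
#' s <- staffing_scenario("added monitor staffing", hourly_rate = 15,
#'                        fte_added = 0.5, hours_per_day = 24, n_days = 270)
#' staffing_scenario_cost(s)  # 48600
#' @export
staffing_scenario <- function(label, hourly_rate, added_hours = NULL,
                              fte_added = NULL, hours_per_day = NULL,
                              n_days = NULL) {
  label <- check_string(label, "label")
  hourly_rate <- check_number(hourly_rate, "hourly_rate", min = 0)
  if (is.null(added_hours)) {
    if (is.null(fte_added) || is.null(hours_per_day) || is.null(n_days)) {
      abort_invalid(paste("supply `added_hours`, or all of `fte_added`,",
                          "`hours_per_day` and `n_days`"),
                    field = "added_hours")
    }
    added_hours <- check_number(fte_added, "fte_added", min = 0) *
      check_number(hours_per_day, "hours_per_day", min = 0) *
      check_number(n_days, "n_days", min = 0, integer = TRUE)
  } else {
    added_hours <- check_number(added_hours, "added_hours", min = 0)
  }
  structure(
    list(label = label, added_hours = added_hours, hourly_rate = hourly_rate),
    class = "cvm_staffing_scenario"
  )
}

staffing_cost_cents <- function(s) {
  round_half_up(s$added_hours * cents(s$hourly_rate))
}

#' @rdname staffing_scenario
#' @param s A [staffing_scenario()].
#' @export
staffing_scenario_cost <- function(s) {
  stopifnot(inherits(s, "cvm_staffing_scenario"))
  dollars(staffing_cost_cents(s))
}

#' @export
print.cvm_staffing_scenario <- function(x, ...) {
  cat(sprintf("<staffing scenario> %s: %s h @ %s/h = %s\n",
              x$label, format(x$added_hours, big.mark = ","),
              fmt_dollars(cents(x$hourly_rate)), fmt_dollars(staffing_cost_cents(x))))
  invisible(x)
}
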