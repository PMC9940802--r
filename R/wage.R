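#' Nursing wage profile and capacity cost rates
#'
#' TDABC prices an activity at the capacity cost rate of the staff
#' performing it. The rate is built in two steps: the base hourly wage is
#' loaded with fringe benefits (employer-paid benefits as a fraction of
#' salary), then divided by the productivity standard (the fraction of
#' paid time that is productive) to give the effective cost per productive
#' hour. Each step is rounded half-up to cents, the published boundary at
#' which such rates are quoted.
#'
#' Defaults are the 2020 US national average nursing wage of $45/h with
#' the conventional 30% fringe loading and 80% productivity standard,
#' giving a $58.50 loaded and $73.13 effective hourly rate.
#'
#' @param base_hourly_rate Base wage in dollars per hour (>= 0).
#' @param fringe_fraction Fringe-benefit loading as a fraction of base
#'   salary, in \[0, 1\].
#' @param productivity_fraction Productive fraction of paid time, in
#'   (0, 1\].
#' @return `wage_profile()` returns a validated `cvm_wage_profile` object;
#'   the rate accessors return dollars per hour.
#' @examples
#' w <- wage_profile()
#' loaded_hourly_rate(w)     # 58.50
#' effective_hourly_rate(w)  # 73.13
#' @export
wage_profile <- function(base_hourly_rate = 45,
                         fringe_fraction = 0.30,
                         productivity_fraction = 0.80) {
  structure(
    list(
      base_hourly_rate = check_number(base_hourly_rate, "base_hourly_rate", min = 0),
      fringe_fraction = check_number(fringe_fraction, "fringe_fraction", min = 0, max = 1),
      productivity_fraction = check_number(productivity_fraction, "productivity_fraction",
                                           min = 0, max = 1, exclusive_min = TRUE)
    ),
    class = "cvm_wage_profile"
  )
}

loaded_rate_cents <- function(wage) {
  round_half_up(cents(wage$base_hourly_rate) * (1 + wage$fringe_fraction))
}

effective_rate_cents <- function(wage) {
  round_half_up(loaded_rate_cents(wage) / wage$productivity_fraction)
}

#' @rdname wage_profile
#' @param wage A [wage_profile()].
#' @export
loaded_hourly_rate <- function(wage) {
  stopifnot(inherits(wage, "cvm_wage_profile"))
  dollars(loaded_rate_cents(wage))
}

#' @rdname wage_profile
#' @export
effective_hourly_rate <- function(wage) {
  stopifnot(inherits(wage, "cvm_wage_profile"))
  dollars(effective_rate_cents(wage))
}

#' @export
print.cvm_wage_profile <- function(x, ...) {
  cat("<wage profile>\n")
  cat(sprintf("  base      %s/h\n", fmt_dollars(cents(x$base_hourly_rate))))
  cat(sprintf("  fringe    %.0f%%  -> loaded    %s/h\n",
              100 * x$fringe_fraction, fmt_dollars(loaded_rate_cents(x))))
  cat(sprintf("  product.  %.0f%%  -> effective %s/h\n",
              100 * x$productivity_fraction, fmt_dollars(effective_rate_cents(x))))
  invisible(x)
}

#' Donning/doffing activity timing
#'
#' The timed minutes for one full PPE change: putting on (donning) and
#' removing (doffing) gloves, mask, gown and face shield, including hand
#' hygiene. The stopwatch-timed defaults are 4 min donning and 6 min
#' doffing. The hour fraction is kept exact ((don + doff) / 60), never
#' pre-rounded, so that the per-call cost reproduces published figures.
#'
#' @param don_minutes Minutes to don PPE (>= 0).
#' @param doff_minutes Minutes to doff PPE (>= 0).
#' @return A `cvm_activity_timing` object.
#' @examples
#' activity_timing()  # 10 min per PPE change
#' @export
activity_timing <- function(don_minutes = 4, doff_minutes = 6) {
  structure(
    list(
      don_minutes = check_number(don_minutes, "don_minutes", min = 0),
      doff_minutes = check_number(doff_minutes, "doff_minutes", min = 0)
    ),
    class = "cvm_activity_timing"
  )
}

timing_hours <- function(timing) {
  (timing$don_minutes + timing$doff_minutes) / 60
}

#' @export
print.cvm_activity_timing <- function(x, ...) {
  cat(sprintf("<activity timing> don %g min + doff %g min = %g min per PPE change\n",
              x$don_minutes, x$doff_minutes, x$don_minutes + x$doff_minutes))
  invisible(x)
}

per_call_time_cost_cents <- function(timing, wage) {
  round_half_up(effective_rate_cents(wage) * timing_hours(timing))
}

#' Staff-time cost of one averted call
#'
#' The donning/doffing cost avoided each time a patient call is resolved
#' over the audiovisual link instead of an in-room visit: the effective
#' hourly rate times the exact activity-hour fraction, rounded half-up to
#' cents. With default parameters this is $12.19 per call.
#'
#' @param timing An [activity_timing()].
#' @param wage A [wage_profile()].
#' @return Dollars per call.
#' @examples
#' per_call_time_cost(activity_timing(), wage_profile())  # 12.19
#' @export
per_call_time_cost <- function(timing, wage) {
  stopifnot(inherits(timing, "cvm_activity_timing"),
            inherits(wage, "cvm_wage_profile"))
  dollars(per_call_time_cost_cents(timing, wage))
}
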