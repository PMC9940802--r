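#' Generate a synthetic call ledger
#'
#' Simulates the daily process the costing pipeline assumes: each day's
#' monitored-patient census is Poisson with the given mean; total call
#' attempts that day are Poisson with mean `census x call rate`; each
#' attempt independently escalates to an in-room visit with probability
#' `escalation_fraction` (binomial thinning). Averted calls are the
#' non-escalated attempts. This is the simplest process consistent with
#' per-day mean reporting — no epidemic waves, weekday effects or
#' length-of-stay structure.
#'
#' The generator is fully deterministic under a fixed `seed` (the RNG
#' state is scoped with [withr::with_seed()], leaving the caller's
#' state untouched).
#'
#' @param n_days Number of consecutive calendar days (>= 1).
#' @param start_date First ledger date.
#' @param mean_monitored_patients_per_day Poisson mean of the daily
#'   census (>= 0).
#' @param calls_per_monitored_day_rate Call attempts per monitored
#'   patient day (>= 0); 8.9 matches the observed 2020 rate.
#' @param escalation_fraction Probability an attempt requires an in-room
#'   visit, in \[0, 1\].
#' @param seed Integer RNG seed.
#' @param unit_id Unit label written on every record.
#' @return A ledger tibble (see [read_ledger()]).
#' @examples
#' generate_ledger(7, mean_monitored_patients_per_day = 5,
#'                 calls_per_monitored_day_rate = 8.9, seed = 1)
#' @export
generate_ledger <- function(n_days,
                            start_date = "2020-03-16",
                            mean_monitored_patients_per_day = 5,
                            calls_per_monitored_day_rate = 8.9,
                            escalation_fraction = 0,
                            seed = 1,
                            unit_id = "CVM") {
  n_days <- check_number(n_days, "n_days", min = 1, integer = TRUE)
  mean_monitored <- check_number(mean_monitored_patients_per_day,
                                 "mean_monitored_patients_per_day", min = 0)
  rate <- check_number(calls_per_monitored_day_rate,
                       "calls_per_monitored_day_rate", min = 0)
  esc <- check_number(escalation_fraction, "escalation_fraction", min = 0, max = 1)
  seed <- check_number(seed, "seed", integer = TRUE)
  unit_id <- check_string(unit_id, "unit_id")
  start_date <- as.Date(start_date)
  if (is.na(start_date)) abort_invalid("`start_date` must be a date", "start_date")

  withr::with_seed(seed, {
    monitored <- stats::rpois(n_days, mean_monitored)
    attempts <- stats::rpois(n_days, monitored * rate)
    escalations <- stats::rbinom(n_days, attempts, esc)
  })
  tibble::tibble(
    date = start_date + seq_len(n_days) - 1L,
    unit_id = unit_id,
    monitored_patient_days = as.integer(monitored),
    calls_averted = as.integer(attempts - escalations),
    escalations = as.integer(escalations)
  )
}

# total %/% n per day, with the remainder assigned to the earliest days
spread_counts <- function(total, n) {
  base <- total %/% n
  extra <- total %% n
  as.integer(base + (seq_len(n) <= extra))
}

#' Deterministic ledger reproducing the 2020 program aggregates
#'
#' A synthetic daily ledger for 2020-03-16 through 2020-12-31 (291 days,
#' single unit) whose aggregates equal the published totals of the 2020
#' COVID-19 CVM deployment: 19,086 averted calls over 1,378 monitored
#' patient days, of which exactly 5,042 calls fall in the early-scale-up
#' window 2020-03-16..2020-04-18. Only those window totals are
#' contractual; within each window counts are spread near-uniformly with
#' remainders on the earliest days (no daily series was published).
#' Escalations are zero so that averted-call totals match the published
#' figures exactly.
#'
#' @return A ledger tibble (see [read_ledger()]).
#' @examples
#' fixture_ledger_2020() |> aggregate_ledger()
#' @export
fixture_ledger_2020 <- function() {
  start <- as.Date("2020-03-16")
  end <- as.Date("2020-12-31")
  first_end <- as.Date("2020-04-18")
  n_total <- as.integer(end - start) + 1L       # 291 days
  n_first <- as.integer(first_end - start) + 1L # 34 days
  tibble::tibble(
    date = start + seq_len(n_total) - 1L,
    unit_id = "CVM",
    monitored_patient_days = spread_counts(1378L, n_total),
    calls_averted = c(spread_counts(5042L, n_first),
                      spread_counts(19086L - 5042L, n_total - n_first)),
    escalations = 0L
  )
}
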