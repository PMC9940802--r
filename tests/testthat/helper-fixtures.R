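# Shared fixtures built in code.

# Default config with the bookkept 2020 equipment program total ($19,441)
# supplied directly, as the study's accounts recorded it.
config_with_program_total <- function() {
  cost_config(options = list(equipment_total_override = 19441))
}

study_report <- function(config = config_with_program_total()) {
  compute_cost_report(fixture_ledger_2020(), config)
}

study_scenario <- function() {
  staffing_scenario("added monitor staffing", hourly_rate = 15, added_hours = 3240)
}

# a small, fully hand-checkable ledger
tiny_ledger <- function() {
  tibble::tibble(
    date = as.Date(c("2020-03-16", "2020-03-17", "2020-03-18")),
    unit_id = "7W",
    monitored_patient_days = c(1L, 2L, 1L),
    calls_averted = c(2L, 1L, 3L),
    escalations = c(0L, 1L, 0L)
  )
}

random_config <- function() {
  # random but valid parameter set, cent-valued where money-valued
  mix <- stats::runif(1, 0.05, 0.95)
  ppe <- tibble::tribble(
    ~category, ~mode, ~variant, ~usage_rate, ~unit_cost, ~uses_per_unit,
    "gloves", "mixed_variants", "a", mix, sample(1:50, 1) / 100, NA_real_,
    "gloves", "mixed_variants", "b", 1 - mix, sample(1:50, 1) / 100, NA_real_,
    "gown", "simple", NA, NA_real_, sample(50:900, 1) / 100, NA_real_,
    "face_shield", "reusable", NA, NA_real_, sample(100:900, 1) / 100,
    as.numeric(sample(1:20, 1))
  )
  cost_config(
    wage = wage_profile(sample(20:80, 1), stats::runif(1, 0, 0.6),
                        stats::runif(1, 0.5, 1)),
    timing = activity_timing(sample(0:10, 1), sample(1:10, 1)),
    ppe = ppe,
    equipment = equipment_profile(sample(1000:8000, 1), sample(1:5, 1), 365,
                                  sample(0:2000, 1) / 100)
  )
}

random_totals <- function() {
  tibble::tibble(
    total_calls_averted = sample(0:50000, 1),
    total_monitored_patient_days = sample(1:5000, 1)
  )
}
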