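write_lines_tmp <- function(lines) {
  p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

ledger_header <- "date,unit_id,monitored_patient_days,calls_averted,escalations"

test_that("read_ledger maps rows to validated, sorted records", {
  p <- write_lines_tmp(c(ledger_header,
                         "2020-03-17,7W,10,120,4",
                         "2020-03-16,7W,12,160,9",
                         "2020-03-16,8E,3,40,1"))
  led <- read_ledger(p)
  expect_equal(nrow(led), 3)
  expect_equal(led$date, as.Date(c("2020-03-16", "2020-03-16", "2020-03-17")))
  expect_equal(led$unit_id, c("7W", "8E", "7W"))
  expect_equal(led$calls_averted, c(160L, 40L, 120L))
})

test_that("read_ledger errors name the row and field", {
  p <- write_lines_tmp(c(ledger_header,
                         "2020-03-16,7W,12,160,9",
                         "2020-03-17,7W,10,-1,0"))
  expect_error(read_ledger(p), "row 2: calls_averted", class = "cvm_validation_error")

  p2 <- write_lines_tmp(c(ledger_header, "not-a-date,7W,1,1,0"))
  expect_error(read_ledger(p2), "row 1: date", class = "cvm_validation_error")

  p3 <- write_lines_tmp(c("date,unit,monitored_patient_days,calls_averted,escalations",
                          "2020-03-16,7W,1,1,0"))
  expect_error(read_ledger(p3), "header", class = "cvm_validation_error")

  p4 <- write_lines_tmp(c(ledger_header, "2020-03-16,7W,1,1.5,0"))
  expect_error(read_ledger(p4), "calls_averted", class = "cvm_validation_error")

  expect_error(read_ledger(tempfile()), "not found", class = "cvm_validation_error")
})

test_that("duplicate (date, unit) records are rejected", {
  p <- write_lines_tmp(c(ledger_header,
                         "2020-03-16,7W,12,160,9",
                         "2020-03-16,7W,2,30,0"))
  expect_error(read_ledger(p), "duplicate", class = "cvm_validation_error")
})

test_that("ledger write/read round-trips, including comment metadata", {
  led <- generate_ledger(30, mean_monitored_patients_per_day = 4,
                         calls_per_monitored_day_rate = 8.9,
                         escalation_fraction = 0.1, seed = 7)
  p <- withr::local_tempfile(fileext = ".csv")
  write_ledger(led, p, comment = "seed=7")
  expect_identical(read_ledger(p), led)
  expect_match(readLines(p, n = 1), "^# seed=7")
})

test_that("aggregate sums an inclusive window with published-style ratios", {
  agg <- aggregate_ledger(tiny_ledger())
  expect_equal(agg$total_calls_averted, 6L)
  expect_equal(agg$n_calendar_days, 3L)
  expect_equal(agg$mean_calls_per_calendar_day, 2.0)
  expect_equal(agg$total_monitored_patient_days, 4L)
  expect_equal(agg$calls_per_monitored_patient_day, 1.5)
  expect_equal(agg$total_escalations, 1L)
})

test_that("fixture aggregates reproduce the published window totals", {
  led <- fixture_ledger_2020()
  full <- aggregate_ledger(led)
  expect_equal(full$total_calls_averted, 19086L)
  expect_equal(full$total_monitored_patient_days, 1378L)
  expect_equal(round_half_up(full$calls_per_monitored_patient_day * 10) / 10, 13.9)
  first <- aggregate_ledger(led, "2020-03-16", "2020-04-18")
  expect_equal(first$total_calls_averted, 5042L)
})

test_that("aggregation is permutation-invariant and additive over disjoint windows", {
  led <- generate_ledger(60, mean_monitored_patients_per_day = 6,
                         calls_per_monitored_day_rate = 8.9, seed = 11)
  shuffled <- led[sample(nrow(led)), ]
  expect_identical(aggregate_ledger(shuffled), aggregate_ledger(led))

  a <- aggregate_ledger(led, min(led$date), min(led$date) + 29)
  b <- aggregate_ledger(led, min(led$date) + 30, max(led$date))
  whole <- aggregate_ledger(led)
  expect_equal(a$total_calls_averted + b$total_calls_averted,
               whole$total_calls_averted)
  expect_equal(a$total_monitored_patient_days + b$total_monitored_patient_days,
               whole$total_monitored_patient_days)
})

test_that("an empty window is flagged, not silently zero-rated", {
  expect_warning(
    agg <- aggregate_ledger(tiny_ledger(), "2021-01-01", "2021-01-31"),
    class = "cvm_empty_window"
  )
  expect_equal(agg$total_calls_averted, 0L)
  expect_true(is.na(agg$mean_calls_per_calendar_day))
  expect_true(is.na(agg$calls_per_monitored_patient_day))
  expect_error(aggregate_ledger(tiny_ledger(), "2020-04-01", "2020-03-01"),
               class = "cvm_validation_error")
})
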