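test_that("wage loading and productivity adjustment follow the published chain", {
  cases <- list(
    # base, fringe, productivity, loaded, effective
    list(45, 0.30, 0.80, 58.50, 73.13),  # published 2020 parameters
    list(45, 0.00, 1.00, 45.00, 45.00),  # identities at zero fringe / full productivity
    list(30, 0.25, 0.75, 37.50, 50.00)   # hand arithmetic: 30*1.25, 37.50/0.75
  )
  for (cc in cases) {
    w <- wage_profile(cc[[1]], cc[[2]], cc[[3]])
    expect_equal(loaded_hourly_rate(w), cc[[4]])
    expect_equal(effective_hourly_rate(w), cc[[5]])
  }
})

test_that("wage validation names the offending field", {
  expect_error(wage_profile(-1), "base_hourly_rate", class = "cvm_validation_error")
  expect_error(wage_profile(45, 1.5), "fringe_fraction", class = "cvm_validation_error")
  expect_error(wage_profile(45, 0.3, 0), "productivity_fraction",
               class = "cvm_validation_error")
})

test_that("per-call time cost uses the exact minute fraction", {
  w <- wage_profile()
  # 73.13 * 10/60 = 12.188... -> 12.19; the pre-rounded 0.167 h would give 12.21
  expect_equal(per_call_time_cost(activity_timing(4, 6), w), 12.19)
  expect_equal(per_call_time_cost(activity_timing(0, 0), w), 0)
  w60 <- wage_profile(60, 0, 1)
  expect_equal(per_call_time_cost(activity_timing(15, 15), w60), 30)
  expect_error(activity_timing(-1), "don_minutes", class = "cvm_validation_error")
})

test_that("PPE category per-use costs match the catalogue conventions", {
  costs <- ppe_cost_per_use(default_ppe_catalogue())
  expect_equal(costs$cost_per_use[costs$category == "gloves"], 0.08)
  expect_equal(costs$cost_per_use[costs$category == "masks"], 4.25)
  expect_equal(costs$cost_per_use[costs$category == "gown"], 5.00)
  expect_equal(costs$cost_per_use[costs$category == "face_shield"], 0.45)

  solo <- tibble::tibble(category = "x", mode = "mixed_variants", variant = "only",
                         usage_rate = 1, unit_cost = 0.37, uses_per_unit = NA_real_)
  expect_equal(ppe_cost_per_use(solo)$cost_per_use, 0.37)
})

test_that("PPE catalogue validation rejects bad rates and reuse counts", {
  bad_rates <- default_ppe_catalogue()
  bad_rates$usage_rate[bad_rates$variant == "vinyl"] <- 0.4
  expect_error(kit_cost_per_change(bad_rates), "sum", class = "cvm_validation_error")

  bad_reuse <- default_ppe_catalogue()
  bad_reuse$uses_per_unit[bad_reuse$category == "face_shield"] <- 0
  expect_error(kit_cost_per_change(bad_reuse), "uses_per_unit",
               class = "cvm_validation_error")
})

test_that("kit cost per change sums category costs exactly", {
  ppe <- default_ppe_catalogue()
  expect_equal(kit_cost_per_change(ppe), 9.78)
  expect_equal(kit_cost_per_change(ppe[0, ]), 0)
  expect_equal(kit_cost_per_change(ppe[ppe$category == "gloves", ]), 0.08)
})

test_that("equipment cost per day amortizes the purchase and adds cleaning", {
  expect_equal(equipment_cost_per_day(equipment_profile()), 14.11)  # 4.11 + 10.00
  expect_equal(equipment_cost_per_day(equipment_profile(0, 3, 365, 0)), 0)
  expect_equal(equipment_cost_per_day(equipment_profile(3650, 1, 365, 0)), 10)
  expect_error(equipment_profile(4500, 0), "amortization_years",
               class = "cvm_validation_error")
})

test_that("staffing scenario cost is hours times rate, with FTE derivation", {
  expect_equal(staffing_scenario_cost(study_scenario()), 48600)
  expect_equal(staffing_scenario_cost(
    staffing_scenario("none", hourly_rate = 99, added_hours = 0)), 0)
  derived <- staffing_scenario("derived", hourly_rate = 15, fte_added = 0.5,
                               hours_per_day = 24, n_days = 270)
  expect_equal(derived$added_hours, 3240)
  expect_equal(staffing_scenario_cost(derived), 48600)
  expect_error(staffing_scenario("incomplete", hourly_rate = 15, fte_added = 0.5),
               "added_hours", class = "cvm_validation_error")
})

test_that("the full report reproduces the 2020 program decomposition", {
  r <- study_report()
  expect_equal(r$time_savings_cents, 23265834)   # $232,658.34
  expect_equal(r$ppe_savings_cents, 18666108)    # $186,661.08
  expect_equal(r$gross_savings_cents, 41931942)  # $419,319.42
  expect_equal(r$equipment_cost_cents, 1944100)  # bookkept $19,441
  expect_equal(r$net_savings_cents, 39987842)    # $399,878.42
  expect_equal(r$roi, 20.6)
  expect_equal(whole_dollars(r$time_savings_cents), 232658)
  expect_equal(whole_dollars(r$ppe_savings_cents), 186661)
  expect_equal(whole_dollars(r$gross_savings_cents), 419319)
  expect_equal(whole_dollars(r$net_savings_cents), 399878)
})

test_that("without an override the equipment cost is days times the daily rate", {
  r <- compute_cost_report(fixture_ledger_2020(), default_config())
  expect_equal(r$equipment_cost_cents, 1378 * 1411)  # $19,443.58
  expect_false(r$equipment_cost_overridden)
  expect_equal(r$roi, 20.6)  # unchanged at 3 significant figures
})

test_that("an empty program yields zero savings and an undefined ROI", {
  empty <- tibble::tibble(total_calls_averted = 0, total_monitored_patient_days = 0)
  r <- compute_cost_report(empty, default_config())
  expect_equal(r$gross_savings_cents, 0)
  expect_equal(r$net_savings_cents, 0)
  expect_true(is.na(r$roi))
})

test_that("a mid-sized program matches the per-event hand oracle", {
  totals <- tibble::tibble(total_calls_averted = 1000,
                           total_monitored_patient_days = 100)
  r <- compute_cost_report(totals, default_config())
  expect_equal(r$time_savings_cents, 1000 * 1219)  # $12,190
  expect_equal(r$ppe_savings_cents, 1000 * 978)    # $9,780
  expect_equal(r$gross_savings_cents, 2197000)     # $21,970
  expect_equal(r$equipment_cost_cents, 100 * 1411) # $1,411
  expect_equal(r$net_savings_cents, 2055900)       # $20,559
  expect_equal(r$roi, 14.6)
})

test_that("roi() reports 3 significant figures and refuses zero cost", {
  expect_equal(roi(399878, 19441), 20.6)
  expect_equal(roi(0, 1000), 0)
  expect_equal(roi(351278, 68041), 5.16)  # 19,441 + 48,600 denominator
  expect_error(roi(100, 0), "ROI undefined", class = "cvm_validation_error")
  expect_error(roi(100, -5), "ROI undefined", class = "cvm_validation_error")
})
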