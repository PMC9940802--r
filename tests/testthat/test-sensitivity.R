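test_that("the added-staffing scenario reproduces the published adjustment", {
  s <- apply_staffing_scenario(study_report(), study_scenario())
  expect_equal(s$staffing_cost_cents, 4860000)            # $48,600
  expect_equal(s$adjusted_net_savings_cents, 35127842)    # $351,278.42
  expect_equal(whole_dollars(s$adjusted_net_savings_cents), 351278)
  expect_equal(s$adjusted_roi, 5.16)
})

test_that("a zero-cost scenario leaves net and ROI unchanged", {
  r <- study_report()
  s <- apply_staffing_scenario(
    r, staffing_scenario("null", hourly_rate = 15, added_hours = 0))
  expect_equal(s$adjusted_net_savings_cents, r$net_savings_cents)
  expect_equal(s$adjusted_roi, r$roi)
})

test_that("doubling the scenario hours follows the hand oracle", {
  s <- apply_staffing_scenario(
    study_report(),
    staffing_scenario("double", hourly_rate = 15, added_hours = 6480))
  expect_equal(s$staffing_cost_cents, 9720000)           # $97,200
  expect_equal(whole_dollars(s$adjusted_net_savings_cents), 302678)
  # 302,678.42 / (19,441 + 97,200) = 2.5949 -> 2.59 at 3 significant figures
  expect_equal(s$adjusted_roi, 2.59)
})

test_that("any positively costed scenario strictly reduces net and ROI", {
  for (hours in c(1, 100, 5000)) {
    s <- apply_staffing_scenario(
      study_report(), staffing_scenario("s", hourly_rate = 15, added_hours = hours))
    expect_lt(s$adjusted_net_savings_cents, s$base$net_savings_cents)
    # strict on the unrounded ratio; significant-figure display can tie
    expect_lt(s$adjusted_net_savings_cents / s$adjusted_program_cost_cents,
              s$base$net_savings_cents / s$base$equipment_cost_cents)
    expect_lte(s$adjusted_roi, s$base$roi)
  }
})

test_that("a null sweep reproduces the base report row", {
  base <- compute_cost_report(fixture_ledger_2020(), default_config())
  sw <- one_way_sweep(fixture_ledger_2020(), default_config(),
                      "equipment.cleaning_cost_per_day", 10)
  expect_equal(sw$net_savings, dollars(base$net_savings_cents))
  expect_equal(sw$roi, base$roi)
})

test_that("sweeps move net savings and ROI in the expected directions", {
  led <- fixture_ledger_2020()
  n95 <- one_way_sweep(led, default_config(), "ppe.masks.N95.unit_cost",
                       c(2.00, 5.75, 9.00))
  expect_true(all(diff(n95$net_savings) > 0))  # pricier avoided PPE, larger savings

  clean <- one_way_sweep(led, default_config(), "equipment.cleaning_cost_per_day",
                         c(0, 5, 10, 20))
  expect_equal(nrow(clean), 4)
  expect_true(all(diff(clean$net_savings) < 0))
  expect_true(all(diff(clean$roi) < 0))
})

test_that("sweeps are pure and repeatable", {
  cfg <- default_config()
  before <- config_digest(cfg)
  sw1 <- one_way_sweep(fixture_ledger_2020(), cfg, "wage.base_hourly_rate",
                       c(30, 45, 60))
  sw2 <- one_way_sweep(fixture_ledger_2020(), cfg, "wage.base_hourly_rate",
                       c(30, 45, 60))
  expect_identical(sw1, sw2)
  expect_identical(config_digest(cfg), before)
})

test_that("breakeven rate matches the closed form and zeroes the pipeline", {
  be <- breakeven_calls_per_monitored_day(default_config())
  expect_equal(be, 1411 / 2197)  # 14.11 / (12.19 + 9.78)
  expect_equal(round(be, 3), 0.642)
  # per monitored day, net at the breakeven rate vanishes to within a cent
  net_per_day <- be * 2197 - 1411
  expect_lt(abs(net_per_day), 1)

  free <- set_config_value(
    set_config_value(default_config(), "equipment.purchase_cost", 0),
    "equipment.cleaning_cost_per_day", 0)
  expect_equal(breakeven_calls_per_monitored_day(free), 0)

  doubled <- set_config_value(
    set_config_value(default_config(), "equipment.purchase_cost", 9000),
    "equipment.cleaning_cost_per_day", 20)
  expect_equal(breakeven_calls_per_monitored_day(doubled), 2 * be)

  zero_saving <- cost_config(wage = wage_profile(0, 0, 1),
                             timing = activity_timing(0, 0),
                             ppe = default_ppe_catalogue()[0, ])
  expect_error(breakeven_calls_per_monitored_day(zero_saving), "breakeven",
               class = "cvm_validation_error")
})
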