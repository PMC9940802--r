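---
title: "Costing a continuous virtual monitoring program with TDABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing a continuous virtual monitoring program with TDABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvmcost)
```

## The problem and the model

When a hospital isolates infectious patients, every in-room nursing
visit requires a full personal protective equipment (PPE) change:
donning and doffing gloves, mask, gown and face shield, with hand
hygiene. A continuous virtual monitoring (CVM) station — an in-room
audiovisual telehealth monitor — lets staff resolve many patient calls
remotely. Each call resolved without entering the room (an *averted
in-person interaction*) saves one donning/doffing cycle of nursing time
and one PPE change of materials; calls that *escalate* to an in-room
visit save nothing and are tracked separately.

`cvmcost` prices this with time-driven activity-based costing (TDABC):
an activity costs the time it takes multiplied by the capacity cost rate
of the resource performing it. The capacity cost rate is built from the
base wage by loading fringe benefits and dividing by the productivity
standard (the fraction of paid time that is productive); the activity
time is the stopwatch-timed donning plus doffing minutes. Against the
savings stands the program's equipment cost, which accrues per
*monitored patient day* — one CVM device serves one isolated patient at
a time, so device-days equal monitored patient days; there is no
sharing model.

## Parameters, units and defaults

The package defaults are the parameter set of a 2020 CVM deployment for
COVID-19 patients, so `default_config()` with no arguments prices that
program:

| parameter | default | unit | role |
|---|---|---|---|
| `base_hourly_rate` | 45 | $/h | national average nursing wage |
| `fringe_fraction` | 0.30 | — | employer-paid benefits loading |
| `productivity_fraction` | 0.80 | — | productive fraction of paid time |
| `don_minutes`, `doff_minutes` | 4, 6 | min | timed PPE change |
| gloves | 0.5 × $0.06 + 0.5 × $0.10 | $/pair | vinyl/nitrile usage mix |
| masks | 0.3 × $0.75 + 0.7 × $5.75 | $/mask | 3-ply/N95 usage mix |
| gown | $5.00 | $/use | single-use |
| face shield | $4.50 / 10 uses | $/use | reusable amortization |
| `purchase_cost` | 4500 | $ | CVM device and cart |
| `amortization_years` | 3 | yr | linear, 365 days/year |
| `cleaning_cost_per_day` | 10 | $/day | daily device cleaning |

These chain to a $58.50 loaded and $73.13 effective hourly rate, $12.19
of staff time per averted call, $9.78 per PPE change, and $14.11 per
monitored patient day.

```{r}
glance(compute_cost_report(fixture_ledger_2020(), default_config()))
```

## Numerical conventions

Design choices here were genuinely open and are fixed as follows:

* **Integer-cent currency.** All amounts are whole cents held in
  doubles (exact far beyond any program scale); savings identities
  (`gross = time + PPE`, `net = gross − equipment`) hold exactly.
* **Rounding pipeline.** Each published unit-cost boundary — loaded
  rate, effective rate, per-call time cost, per-use PPE category cost,
  per-day amortized device cost — is rounded half-up to cents *before*
  multiplication by integer counts. Rounding at these boundaries is the
  only convention under which component totals are exact integer
  multiples of quoted unit costs, and it makes savings exactly linear
  in the call count.
* **Round half-up, everywhere.** Ties go away from zero (73.125 →
  73.13), as in commercial ledgers — not banker's rounding. The
  implementation adds a 1e-7 guard before truncation to absorb binary
  floating-point droop at exact half-cent boundaries (5850/0.8 is
  7312.4999…95 in doubles); the guard is five orders of magnitude below
  a cent, so it can never flip a genuinely sub-half value.
* **Exact minute fraction.** The activity-hour fraction is kept as
  (don + doff)/60, never pre-rounded to 0.167 h: with the default wage
  chain the exact fraction gives $12.19 per call, the pre-rounded
  figure $12.21.
* **365-day years.** Amortization ignores leap years; 2020's 366th day
  would change the per-day device cost.
* **ROI at 3 significant figures**, the single convention consistent
  with reporting both 20.6 and 5.16.
* **Window day counts are inclusive** of both endpoints, fixed for the
  per-calendar-day ratios; per-day ratios are displayed to 1 decimal
  place while the stored columns keep full precision.
* **Degenerate inputs.** A zero-cost program has no defined ROI:
  `compute_cost_report()` reports `NA`, and the scalar `roi()` helper
  refuses a non-positive denominator outright rather than returning an
  infinity. An empty aggregation window warns and reports `NA` ratios,
  never a silent zero rate.

## The equipment program cost and its override

The computed program cost is `monitored patient days × per-day device
cost` — with defaults, 1,378 × $14.11 = $19,443.58. Deployed programs
often carry a bookkept equipment total instead (the 2020 program's
accounts recorded $19,441, $2.58 off the day-count formula — a
difference whose origin the available aggregates do not resolve).
`options$equipment_total_override` accepts such a directly stated total;
the formula remains the default behaviour. The override also pins the
program cost during sweeps, so sweeps over equipment parameters should
use a formula-based (non-overridden) configuration.

## Sensitivity analysis

The staffing scenario treats added monitor staffing as a semi-fixed
*program* cost: it reduces net savings dollar-for-dollar and joins the
ROI denominator — it is not netted out of the gross savings line items.
That convention is what makes an added 0.5 FTE around the clock
(3,240 h at $15/h, $48,600) take the 2020 program from ROI 20.6 to 5.16.

```{r}
report <- fixture_ledger_2020() |>
  compute_cost_report(cost_config(options = list(equipment_total_override = 19441)))
glance(apply_staffing_scenario(report, default_scenarios()[[1]]))
```

`one_way_sweep()` and `breakeven_calls_per_monitored_day()` are engine
extensions beyond that single scenario: the sweep re-runs the whole
pipeline per candidate value of one configuration leaf, and the
breakeven rate is the closed form `per-day device cost / per-call
saving` — exact because savings are linear in call count at fixed unit
costs, so no root-finder is needed (the closed form is additionally
verified against the pipeline in the test suite).

```{r}
breakeven_calls_per_monitored_day()   # calls per monitored patient day
```

At the default parameters a monitored day pays for itself at 0.642
averted calls — far below the observed 8.9 per monitored day.

## What the synthetic generator emulates — and what it does not

`generate_ledger()` draws each day's monitored-patient census from a
Poisson law, call attempts from a Poisson law with mean `census × call
rate`, and escalations by binomial thinning of attempts. This is the
simplest process consistent with per-day mean reporting, and it is what
the test suite uses to exercise aggregation, serialization and rate
recovery (the empirical call rate converges to the specified rate; tests
assert recovery within 3 standard errors at fixed seeds, with 1,000-day
ledgers). Real deployment data differ in ways the generator deliberately
omits: epidemic waves and weekday structure in the census, overdispersed
call counts, patient length-of-stay correlation, and unit-level
heterogeneity. Passing tests therefore validate the *accounting engine*
and the generator's own contracts, not any forecast of real call
volumes.

`fixture_ledger_2020()` is different in kind: a deterministic synthetic
ledger whose window aggregates equal the published 2020 totals (19,086
averted calls, 1,378 monitored patient days, 5,042 calls in the
2020-03-16..04-18 scale-up window). Only those totals are contractual —
no daily series was published, so counts are spread near-uniformly with
remainders on the earliest days, and escalations are zero so averted-call
totals match exactly. Published per-day means quoted alongside those
totals (e.g. "153 calls per day" in the first window) depend on an
unstated day-count convention and are deliberately not fixture
contracts.

## Known limitations

* Savings from avoided infections and staff exposure are outside the
  model, as are mask fit-testing and training costs (incurred with or
  without CVM) and any clinical-outcome or satisfaction measurement.
* Single currency, single-year horizon: no discounting, inflation
  adjustment, or multi-year budget impact.
* The ledger is daily per unit; per-call timestamps are out of scope.
* Monitored patient days are ledger inputs, not inferred from census or
  admissions data.
* Sensitivity analysis is deterministic (one-way); no probabilistic
  sensitivity analysis over cost distributions.
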