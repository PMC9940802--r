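# cvmcost

Time-driven activity-based costing (TDABC) for hospital **continuous
virtual monitoring (CVM)** programs.

During isolation-heavy care (COVID-19 wards, immunocompromised patients),
every in-room nursing visit costs a full personal protective equipment
(PPE) change — timed donning and doffing plus single-use materials. A CVM
station (an in-room audiovisual telehealth monitor) lets staff resolve
many patient calls remotely, averting those visits. `cvmcost` turns a
daily call ledger and a cost configuration into the program's savings
decomposition and return on investment, for hospital finance and
telehealth teams evaluating or defending such a program.

## The model

TDABC prices an activity as *time required × capacity cost rate*. For an
averted call, with base wage $w$, fringe fraction $f$, productivity
fraction $p$, and donning/doffing minutes $m$:

```
loaded rate     = w (1 + f)                    (rounded to cents)
effective rate  = loaded / p                   (rounded to cents)
time cost/call  = effective × m / 60           (rounded to cents)
```

The PPE cost per change is the sum of category per-use costs
(usage-rate-weighted variant mixes for gloves and masks, per-use
amortization for reusable face shields, unit cost for gowns). Device cost
accrues per monitored patient day as the linearly amortized purchase
price plus daily cleaning. For $n$ averted calls over $d$ monitored
patient days:

```
gross savings  = n × time cost/call + n × PPE cost/change
net savings    = gross − program equipment cost     (= d × per-day cost)
ROI            = net / program equipment cost
```

Every per-event unit cost is rounded half-up to cents **before**
multiplying by the integer counts, and all currency lives in exact
integer cents, so the identities above hold to the cent.

## Worked example

The bundled deterministic ledger reproduces the aggregates of a 2020
CVM deployment for COVID-19 patients (19,086 averted calls, 1,378
monitored patient days):

```r
library(cvmcost)

fixture_ledger_2020() |>
  compute_cost_report(default_config())
#> Continuous virtual monitoring cost-savings report
#>   19,086 averted calls over 1,378 monitored patient days
#>   unit costs: $12.19/call staff time, $9.78/PPE change, $14.11/monitored day
#>   Staff-time savings          $232,658.34  (55.5% of gross)
#>   PPE savings                 $186,661.08  (44.5% of gross)
#>   Gross savings               $419,319.42
#>   Program equipment cost       $19,443.58
#>   Net savings                 $399,875.84
#>   ROI: 20.6
```

Each averted call saved $12.19 of productivity-adjusted nursing time and
$9.78 of PPE; the program's device cost (amortization plus cleaning) is
a small fraction of the gross savings, so the program returns roughly
$20.60 per dollar of equipment spend. A semi-fixed staffing addition is
assessed as a sensitivity scenario:

```r
fixture_ledger_2020() |>
  compute_cost_report(cost_config(options = list(equipment_total_override = 19441))) |>
  apply_staffing_scenario(default_scenarios()[[1]])
#> Scenario `added monitor staffing`
#>   staffing cost          $48,600.00 (3,240 h @ $15.00/h)
#>   adjusted net          $351,278.42 (base $399,878.42)
#>   adjusted ROI                 5.16 (base 20.6)
```

(Here the program's bookkept equipment total of $19,441 is supplied via
`equipment_total_override`.) One-way sweeps and the breakeven call rate
generalise this:

```r
one_way_sweep(fixture_ledger_2020(), default_config(),
              "equipment.cleaning_cost_per_day", c(0, 5, 10, 20))
breakeven_calls_per_monitored_day()   # 0.642 averted calls/monitored day
```

Results are tidy-friendly: `tidy()` gives the component breakdown,
`glance()` a one-row dollar summary, `autoplot()` the savings figure.
A command-line wrapper lives at
`system.file("cli", "cvmcost.R", package = "cvmcost")` with `compute`,
`simulate`, `sweep` and `breakeven` subcommands.

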