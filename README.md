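# harvestplan

Decision support for seed-corn planting: forecast daily growing degree
units (GDUs), turn planting windows and heat requirements into harvest-week
eligibility, and schedule planting with mixed-integer linear programs so
weekly harvest totals respect storage capacity using a minimum number of
harvesting weeks.

## Who this is for

Production planners and agronomic modellers who must decide, for hundreds
of corn populations with individual planting windows `[P_iE, P_iL]`, heat
requirements, and harvest quantities `Q_ic` (ears), *when to plant* so that
the resulting weekly harvest intake never exceeds a site's storage capacity
`C_s` — or, for a site not yet built, what the minimum sufficient capacity
would be.

## The method

**Stage 1 — GDU forecasting.** Daily GDU history is windowed into sliding
samples (two years of features, 1.5 years = 547 days of responses, one-day
shift) and fed to a one-dimensional convolutional network — conv(128
filters, kernel 2, ReLU) → max-pool(2) → dense(100, ReLU) → linear(547) —
trained with Adam on MSE, fully seeded, implemented natively in R. Any
external forecaster (e.g. a TBATS fit) can be plugged in through the same
contract; `seasonal_naive()` is the built-in benchmark. Errors are reported
as MSE and RRMSE = 100·RMSE/mean(observed).

**Stage 2 — scheduling.** A population planted on day `d` matures when
cumulative GDUs reach its requirement (counting the planting day, capped at
120 days); the week of that maturity day defines the harvest-week matrix
`H[i, d]` and the binary eligibility matrix `a[i, j]`. With assignment
variables `X_ij ≤ a_ij`, `Σ_j X_ij = 1`:

* *fixed capacity*: minimise the number of harvesting weeks `Σ_j Y_j`
  subject to `Σ_i Q_i X_ij ≤ C_s · Y_j`;
* if infeasible, a three-step sequence finds the minimal uniform extra
  capacity `Z`, concentrates it on the *peak weeks* (per-week `m_j ≤ Z`
  of minimal total), and re-minimises the week count under `C_s + m_j`;
* *flexible capacity*: first minimise the capacity `C_z` itself, then
  schedule at `C_z`.

Chosen weeks map back to planting dates through `H` (earliest in-window
day). Models are solved exactly (MIP gap 0) by HiGHS via a bundled
`python`/scipy worker behind a swappable backend contract.

## Worked example

Synthetic two-year GDU history for a cool site, 60 populations, fixed
weekly capacity of 2,500 ears:

```r
library(harvestplan)
series <- gen_gdu_series(site_profile_site0(n_years = 2))
pops   <- gen_population_table(population_profile(n_populations = 60, seed = 4), series)
H      <- build_harvest_week_matrix(pops, series)
elig   <- build_eligibility_matrix(H)
inst   <- scheduling_instance(pops, elig, capacity = 2500)
plan   <- run_fixed_capacity(inst, H)
plan
#> <harvest_plan> path: single
#> <harvest_schedule> 60 populations over 11 week(s); status OPTIMAL
#>   weeks: 19, 21, 22, 24, 25, 26, 28, 29, 31, 33, 35
```

The capacity was feasible, so the single base solve suffices (`path:
single`): all 17,472 ears are harvested in 11 weeks, none exceeding 2,500
ears. Per-population decisions and the summary:

```r
head(tidy(plan), 4)
#> # A tibble: 4 × 4
#>   population harvest_week quantity planting_day
#>   <chr>             <int>    <dbl>        <int>
#> 1 p001                 24      120           75
#> 2 p002                 31      235          116
#> 3 p003                 24      151           56
#> 4 p004                 33      284          135

evaluate_schedule(plan)
#> # A tibble: 1 × 5
#>   max_abs_deviation median_abs_deviation weeks_used last_week proposed_capacity
#>               <dbl>                <dbl>      <int>     <int>             <dbl>
#> 1              1949                  694         11        35                NA
```

`p001` should be planted on day-of-season 75 and will be harvested in week
24; the worst week leaves 1,949 ears of slack against capacity. Lowering
the capacity below the feasible minimum switches `run_fixed_capacity()` to
the three-step path and reports the peak weeks (`plan$peak_weeks`) and
their extra capacity `m_j`; `run_flexible_capacity()` instead proposes the
minimum sufficient capacity. `autoplot(plan)` draws the weekly allocation
against capacity, and `run_pipeline()` drives the whole
forecast → maps → schedule → evaluate chain from CSV inputs, writing all
artifacts (a thin CLI wrapper lives at `inst/cli/harvestplan`).

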