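---
title: "Methods: GDU forecasting and capacity-aware planting schedules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GDU forecasting and capacity-aware planting schedules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(harvestplan)
```

## The problem

Commercial seed-corn production schedules hundreds of genetically distinct
*populations*, each with its own admissible planting window
$[P_{iE}, P_{iL}]$, heat requirement, and expected harvest quantity $Q_{ic}$
(in ears, per demand scenario $c$). A population is ready for harvest once
its cumulative **growing degree units** (GDUs, degree-days) since planting
reach a breed-specific threshold, and the whole population must then be
harvested within one week. Weekly intake at a site is limited by storage
capacity $C_s$. Choosing planting days therefore means choosing harvest
weeks, and a good plan packs the season's harvest into few weeks without
ever exceeding capacity.

harvestplan implements this as a two-stage pipeline:

1. **Forecasting** — predict the coming season's daily GDUs from history,
   with a one-dimensional convolutional network (1D-CNN) trained on sliding
   windows, benchmarked against a pluggable seasonal forecaster.
2. **Scheduling** — convert planting windows plus GDU requirements into
   week-eligibility, then solve mixed-integer linear programs (MILPs) that
   assign each population a harvest week.

## Stage 1: agronomic bookkeeping

### Accumulation and the maturity cap

`accumulate_to_threshold()` returns the smallest $k$ such that the GDUs of
days $d, d+1, \dots, d+k-1$ sum to at least the requirement. Three
conventions are deliberate and documented rather than inherited:

* the planting day's own GDUs count toward the threshold, and $k = 1$ means
  the crop matures on the planting day, so the maturity day is $d + k - 1$;
* a threshold met exactly at a day boundary counts that day ($\ge$, not $>$);
* accumulation is capped at `max_harvest_days` (default 120), the agronomic
  upper bound for corn, which otherwise matures in roughly 95–110 days.
  A planting day that cannot reach the requirement within the cap (or before
  the series ends) is simply not a valid planting day.

### Late-planting adjustment

Corn planted into a cooling season matures with a lower heat requirement.
`maturity_config()` accepts an optional adjustment — a cutoff day-of-season
and a flat GDU reduction (suggested 110 degree-days, the reported average
for June versus May plantings in the US corn belt) — applied to plantings at
or after the cutoff and clamped at zero. It is off by default because it is
a site-specific judgement call, not a universal rule.

### Weeks, H and a

Days-of-season are 1-based; week $j$ covers days $7(j-1)+1 \dots 7j$, i.e.
$j = \lceil d/7 \rceil$, over a 70-week season by default. The harvest-week
matrix $H_{id}$ maps every in-window planting day $d$ of population $i$ to
the week containing its maturity day (or `NA`). The eligibility matrix
$a_{ij} = 1$ iff some in-window day of $i$ matures in week $j$. Populations
whose $a$-row is all zeros cannot be scheduled at all; they are reported
(message + `unschedulable_populations()`) and excluded from the MILPs rather
than raised as errors, so a caller can surface them to an agronomist.

## Stage 2: the scheduling MILPs

All models share binary assignment variables $X_{ij}$ (population $i$
harvested in week $j$), restricted to $X_{ij} \le a_{ij}$, with
$\sum_j X_{ij} = 1$. Weekly load is $\sum_i Q_{ic} X_{ij}$.

**Fixed capacity (base).** Minimise the number of harvesting weeks
$\sum_j Y_j$ subject to $\sum_i Q_{ic} X_{ij} \le C_s Y_j$. The $C_s Y_j$
coupling is the natural big-M form (the capacity itself is the tightest
valid M), kept as-is rather than reformulated. Infeasibility is a returned
value, not an exception: it is the signal that triggers the three-step path.

**Three-step path (infeasible fixed capacity).**

1. *Capacity model*: minimise the uniform extra capacity $Z \ge 0$ with
   per-week caps $C_s + Z$.
2. *Peak-week model*: minimise $\sum_j m_j$ with per-week caps $C_s + m_j$
   and $m_j \le Z$. The weeks with $m_j > 0$ are the peak weeks a
   decision-maker must provision for.
3. *Allocation model*: re-minimise $\sum_j Y_j$ with the $m_j$ frozen as
   constants, i.e. caps $(C_s + m_j) Y_j$ — freezing keeps the model linear.

**Flexible capacity.** Step 1 minimises the capacity $C_z$ itself (no
$Y_j$ at this step); step 2 is the base model run at $C_s := C_z$.

Finally the chosen week is mapped back to a planting date as the *earliest*
in-window day $d$ with $H_{id} = j$ — the tie-break among equally valid
planting days is earliest-first, which maximises schedule slack downstream.

### Numerical choices

* $Z$, $m_j$ and $C_z$ are solved as continuous variables (the formulations
  only require $\ge 0$). With integer quantities the optima land on
  integers anyway; a relative $10^{-9}$ slack absorbs solver round-off when
  a continuous optimum is passed into the next step's bounds.
* The feasibility check that routes between the single-solve and three-step
  paths is a full base-model solve; statuses other than optimal/infeasible
  (time limit, solver error) raise with the stage named, never a silent
  fallback.
* MIP relative gap is 0 (objectives are small integers and ear counts);
  the per-solve time limit defaults to 600 s and is configurable
  (`options(harvestplan.solver_time_limit = ...)`).
* Ties among equally good schedules are left to the solver, which is
  deterministic for a fixed model; the run log records the backend.

### Solver backend

The models are formulated sparsely in R ($X$ variables exist only where
$a_{ij} = 1$) and solved through a backend contract (`hp_milp()`): an exact
branch-and-bound solver (HiGHS, reached through `scipy.optimize.milp` in a
small `python` worker shipped with the package). The worker is started once
per session and answers requests over a localhost socket; if that path is
unavailable each solve falls back to a one-shot subprocess. Any exact MIP
solver could stand behind the same contract.

## Stage 1 in detail: forecasting

### Windowing

`make_sliding_windows()` turns a daily series into samples whose features
are `lookback` consecutive days and whose responses are the following
`horizon` days, shifting by one day between samples — so a series of length
$T$ yields $T - \text{lookback} - \text{horizon} + 1$ samples. Defaults are
lookback 730 (two years) and horizon 547 (1.5 years); both are configurable
since the construction works for any season length.
`chronological_split()` never shuffles; the default boundary puts 85% of
samples in training, mirroring a design that trains on the first 8.5 of 10
years.

### The 1D-CNN

The network is input → 1D convolution (128 filters, kernel 2, ReLU) →
max-pool (2) → dense (100, ReLU) → linear output (547), trained with Adam
on mean squared error. The forward pass, backpropagation and Adam updates
are implemented directly in R matrix code; training is fully seeded
(weights and batch shuffling), so a fit is bit-reproducible. The reference
hyperparameters above define the architecture; the training schedule
(optimizer settings, 50 epochs, batch 32 by default) is configurable, as
the original values were chosen by trial and error and any fixed recipe is
somewhat arbitrary. Inputs and outputs are min-max scaled on the training
range (default on): raw-scale training of a ReLU network on degree-day
magnitudes is needlessly fragile, and scaling is inverted at prediction.
Prediction is one-shot — the full horizon in a single forward pass — not
recursive.

### The benchmark contract

The comparison forecaster is a contract, not a fixed model: anything that
maps the last `lookback` days to `horizon` values can be plugged in
(`plugin_forecaster()`), including a library TBATS fit with a 365.25-day
season. The always-available reference is `seasonal_naive(period)`, which
repeats the last observed cycle; on a noiseless periodic series it is exact,
which gives the test suite a sharp anchor.

### Metrics

`forecast_metrics()` reports MSE and
$\mathrm{RRMSE} = 100 \cdot \mathrm{RMSE} / \overline{y}_{\text{obs}}$ in
percent. This normalisation is chosen because it is scale-invariant and
consistent with reported GDU error magnitudes for series whose daily means
sit in the 7–13 degree-day range; it is undefined (flagged `NA`) when the
observed mean is not positive.

## Synthetic data

The original two-site challenge dataset is not publicly packaged, so seeded
generators emulate its statistical structure:

* `gen_gdu_series()` draws
  $\mathrm{clamp}_0(\mu + A\sin(2\pi t/365 + \phi) + \varepsilon_t)$,
  $\varepsilon_t \sim N(0, \sigma^2)$. The canned profiles are site 0
  $(\mu, A, \sigma) = (7.5, 2.0, 0.6)$ — cool, low-variance, >90% of days
  below 10 degree-days — and site 1 $(11.5, 2.5, 1.0)$ — warmer, higher
  variance, mainly above 10 — matching the qualitative contrast and the
  roughly 4–16 degree-day range of the case-study sites. The sinusoid +
  Gaussian form is our choice; only ranges and variance orderings are known.
  The warm peak sits mid-season by default (phase $-\pi/2$).
* `gen_population_table()` draws planting windows uniformly (starts over
  days 1–150, lengths 7–21) and *calibrates* the GDU requirement by drawing
  a target maturity of 95–118 days and multiplying by the series' mean
  daily GDU, so typical maturities land in the corn-realistic 95–120-day
  band. Quantities are uniform on 50–500 ears, two scenarios per
  population. Every generated population is guaranteed at least one
  eligible week (bounded resampling). Population count and quantity scale
  are plausible defaults — the real counts were never published.
* `gen_case_fixture()` assembles series + populations + maps + instance.
  Fixed-capacity fixtures come in two flavours derived from the instance's
  own minimum feasible capacity $C_{\min}$ (computed with the flexible
  model): *ample* sets $C_s = \lceil 1.25\,C_{\min} \rceil$ (single-solve
  path guaranteed) and *tight* sets $C_s < C_{\min}$ (three-step path
  guaranteed).

What the generators do **not** emulate: multi-year climate trends, multiple
seasonalities, spatial correlation between sites, or any weather-API
realism. Passing tests on synthetic fixtures therefore demonstrates the
pipeline's correctness and the solvers' optimality, not forecast skill on
real weather.

## Evaluation metrics

`evaluate_schedule()` reports, over **used weeks only**, the maximum and
median absolute deviation $|C - \text{weekly total}|$, plus the number of
harvesting weeks and the last harvesting week. Idle weeks are excluded
because including them would swamp the median with full-capacity
deviations and measure season length, not allocation quality. "How many
weeks" is reported both as the count of harvesting weeks and as the index
of the last one, since the two readings genuinely differ and both are
informative. Flexible-capacity runs echo the proposed capacity; fixed runs
report it as `NA`.

## Test problem sizes

The suite solves the toy three-population instance exactly; checks all four
MILP objectives against exhaustive enumeration on 30 random instances of up
to 6 populations × 8 weeks (each population eligible for 1–3 weeks, which
keeps enumeration sharp and fast); and audits the full invariant set on a
panel of 20 end-to-end fixtures of 30–200 populations over 70 weeks, mixed
across ample/tight/flexible flavours and both site profiles. The
forecasting benchmark uses a scaled-down geometry (period-30 sinusoid,
noise SD 0.4, lookback 60, horizon 30, 8 filters, 32 dense units, 120
epochs) so a full train-and-compare runs in seconds while preserving the
qualitative result: the trained CNN's test RRMSE (≈5–6%) beats the
seasonal-naive reference (≈6.5–8%).

## Known limitations

* The CNN trains on CPU in R; the reference 730→547 architecture is
  buildable and trainable but slow at that scale — the package is tuned for
  the scaled-down geometries used in practice here.
* One population cannot be split across weeks (a modelling assumption, kept).
* Scenarios are mutually exclusive: one quantity column per solve.
* Multi-site joint scheduling and the quadratic joint
  capacity-and-weeks formulation are out of scope.
* The MILP backend needs `python` with scipy on the PATH; without it the
  scheduling half of the package raises a clear error.
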