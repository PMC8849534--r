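---
title: "Methods: simulating the work-stress, cortisol and allostatic-load pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating the work-stress, cortisol and allostatic-load pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allostasim)
```

## The model

`allostasim` simulates how repeated activation of the
hypothalamus–pituitary–adrenal (HPA) axis by work stressors can, over
months, produce disease. The causal chain is deliberately minimal and
runs through four coupled equations, integrated on a half-hour grid:

1. **Impulses.** All HPA activity is driven by *impulses* of binary
   intensity and fixed 30-minute duration. *Night impulses* arise from a
   circadian process: their daily count is Poisson with a person's mean
   rate $\lambda_N$, and each onset falls an $\mathrm{Exp}(1\,/\mathrm{h})$
   offset before that day's waking time, so they cluster just before
   awakening. *Work impulses* have daily Poisson counts with mean
   $\lambda_W$ (scaled to the day length, see below) and onsets uniform
   over the working hours. Free days carry no work impulses. The gridded
   impulse count is $\sum I_t$; simultaneous impulses add.

2. **Cortisol.** $dC/dt = -\rho_C\,C_t + \kappa_{HPA} \sum I_{t-\tau}$:
   production proportional to the impulse count delayed by $\tau$, and
   first-order decay with a person-specific constant $\rho_C$. The
   pre-waking cluster of night impulses produces the familiar cortisol
   awakening response (the *morning peak*, about half an hour after
   waking), followed by a declining day profile.

3. **Allostatic strain.** $dS/dt = -\rho_R\,S_t + C_t$: the reversible
   burden cortisol places on regulatory systems, recovering at rate
   $\rho_R$ (the elastic stretch of the rubber-band analogy).

4. **Allostatic load and disease.**
   $dL/dt = \max(0, S_t - \epsilon_L)$: strain in excess of the
   allostatic threshold accrues irreversibly (plastic deformation), and
   $D_t = (L_t \ge \epsilon_D)$ flips a persistent disease state once
   load reaches the disease threshold (failure). At the threshold
   boundaries, strain exactly at $\epsilon_L$ contributes nothing, while
   load exactly at $\epsilon_D$ counts as diseased — both conventions
   follow the printed piecewise definitions.

The strain, load and disease scales are intentionally unitless: absolute
times-to-disease are meaningless, and every analysis in the package is
comparative (odds ratios per SD of exposure, relative risks between
workweek configurations).

## Person-level heterogeneity and the two scenarios

`build_population()` gives each person three traits:

* $\rho_C$ — drawn from $\mathrm{N}(0.52, 0.05^2)$ per hour. We read the
  second parameter as a standard deviation of 0.05/h because the implied
  mean half-life $60\ln 2/\rho_C \approx 80$ minutes then sits inside the
  physiological 60–90 minute range. Non-positive draws (probability
  $\sim 10^{-25}$) are redrawn, with a bounded retry budget.
* $\lambda_W$ — per standard 8-hour working day. Gamma$(k=3,\theta=6)$
  for a realistically skewed population; the epidemiological analyses use
  $\mathrm{U}(1,50)$ instead, spreading exposure evenly to sharpen effect
  detection without changing the mechanism.
* $\lambda_N$ — under **Scenario I**, drawn independently from
  Gamma$(k=3,\theta=14)$ (uncorrelated night and work rates). Under
  **Scenario II**, $\lambda_N = \lambda_W + $ Gamma$(k=1,\theta=8)$,
  modelling anticipation: people facing more work stressors mount larger
  pre-waking cortisol surges. Scenario II is implemented exactly as this
  sum even though its night-rate mean ($\approx 26$ when
  $\lambda_W \sim$ Gamma$(3,6)$) is below Scenario I's 42; the coupling
  distribution is exposed in `scenario_spec()` so users can recalibrate.

$\rho_R$, $\epsilon_L$ and $\epsilon_D$ are shared by all persons; giving
them inter-individual variation would only add arbitrary assumptions on
already-unitless scales.

### Day-length scaling and anticipation

Both rates refer to the 8-hour reference day. Longer working days expose
a person to proportionally more work stressors, so the effective daily
work rate is $\lambda_W \times h/8$ for an $h$-hour day. The anticipation
component of the night rate mirrors the upcoming workday, so under
Scenario II it scales the same way: the effective nightly rate is
$\lambda_N + \lambda_W(h/8 - 1)$, identical to the plain sum at $h = 8$.
This coupling is what differentiates workweek configurations: load
accrual is dominated by the morning peak, and with a fixed $\lambda_N$
all configurations of equal weekly hours would be equivalent. The nightly
rate is constant across the days of a configuration, free days included —
we do not model reduced anticipation before free days, nor day-to-day
carry-over of stressor intensity.

## Numerical choices

* **Grid.** `dt = 0.5` h (two samples per hour), matching the 30-minute
  impulse duration; an impulse occupies exactly the grid step containing
  its onset, which keeps the count-conservation invariant exact.
* **Integration.** Forward Euler throughout, with the explicit
  convention that step $k \to k+1$ uses start-of-step values
  ($C_k$, $S_k$) and the delayed impulse count $\sum I_{k-d}$,
  $d = \tau/dt$. Steps with $dt\,\rho \ge 1$ are rejected as unstable.
  Because Euler's per-step decay $1 - \rho_C dt = 0.74$ understates the
  exact factor $e^{-0.26} \approx 0.771$, `dynamics_params(decay_mode =
  "exact")` offers an exponential-decay variant that preserves the true
  half-life at any step size; all qualitative results hold under either
  mode.
* **Load increment.** The load equation is a rate, so the increment is
  multiplied by `dt`. Without it the load scale would depend on the
  sampling frequency, contradicting the continuous-time statement of the
  model; since $\epsilon_L$ and $\epsilon_D$ are arbitrary, only relative
  results matter, and they are unaffected.
* **Initial conditions and pre-roll.** $C_0 = S_0 = L_0 = 0$ at midnight
  of day 0 (a Monday). Day-0 night impulses are drawn behind a 07:00 wake
  and may fall before $t = 0$; a 24-hour pre-roll segment keeps them so
  early-morning cortisol is properly forced, and the pre-roll is excluded
  from every summary.
* **Reproducibility.** Each person receives an independent RNG substream
  derived from the master seed by a prefix-stable construction, so
  enlarging the population never perturbs earlier persons, and the same
  seed gives every person identical night-impulse realizations across
  workweek configurations (common random numbers), which sharply reduces
  the Monte-Carlo variance of relative risks.

## Schedules

Default clock: wake 07:00, work 08:30–16:30, Monday–Friday. The six
benchmark configurations redistribute the same weekly hours: #2 swaps the
Wednesday for the Saturday as a free day, #3 and #4 compress work into 4
and 3 days, #5 and #6 spread it over 6 and 7 short days. At 50 weekly
hours configuration #4 implies 16h40m days that cannot start at 08:30
without crossing midnight; the default start is then advanced just enough
for the window to end at 24:00 (07:20, still after wake). Explicitly
supplied work starts that cross midnight are rejected.

## Diurnal summaries

`day_curve()` aggregates per-person cortisol aligned to waking (day 0 by
default, spanning wake to wake + 16 h; the night window is `from = -4,
to = 0`). `diurnal_indices()` computes the standard trapezoidal
area-under-curve indices AUC~G~ and AUC~I~ and the wake-to-bed slope.
"Bed" is fixed at wake + 16 h, matching the span of the day curves. The
slope uses the two endpoint samples (the simplest reading of a
wake-to-bed slope), with a regression-over-all-points mode available.
Indices are computed on the full half-hour grid rather than a sparse
saliva-sampling protocol; the sampling scheme is configurable by
subsetting the time courses.

## Epidemiological analyses

Disease-by-day is regressed on the z-scored realized mean work impulses
per working day (`stats::glm`, binomial); the exponentiated coefficient
is the odds ratio per SD of exposure, reported capped at 100 (complete
separation otherwise produces arbitrarily large estimates), and undefined
— `NA`, never silently dropped — when the outcome does not vary. The
realized exposure is used rather than the latent $\lambda_W$ because that
is what an observational study could measure; a switch selects the latent
rate.

`run_sweep()` evaluates the odds ratio over a
$3 \times 3 \times 3$ grid of $(\rho_R, \epsilon_L, \epsilon_D)$. The
reference values (0.6, 20, 400) are bracketed geometrically — halved and
doubled — because no canonical grid exists on these arbitrary scales; the
grid is fully user-overridable. Checkpoint days default to 50, 100, 150,
200. Cortisol does not depend on any swept parameter, so each person's
cortisol series is computed once and only the cheap strain/load/threshold
stages are repeated per combination.

`compare_workweeks()` simulates one shared population under all six
configurations with common random numbers and reports cumulative
incidence and relative risk versus the Mon–Fri benchmark.

## Configuration and orchestration

`run_study()` drives the three reference studies from a validated
configuration (`default_config()`, `load_config()`); configuration files
are YAML, and unknown keys or invariant violations fail naming the
offending key. A thin command-line front end ships in
`inst/cli/allostasim.R`.

## What the generator does and does not emulate

The synthetic populations reproduce the *structure* of the data the model
was calibrated against: heterogeneous impulse rates and decay constants,
Poisson day-to-day variation, exponential pre-wake clustering, uniform
work timing, work-free weekends. They do not contain measurement noise,
stressors of variable duration or intensity, evening/non-work stressors,
weekday/weekend differences in night rates, or adaptation of the HPA axis
under chronic stress (hypocortisolism). Passing tests therefore show that
the implementation realizes the stated stochastic model, and that the
model's comparative claims are reproducible — not that real cortisol or
disease data would quantitatively match.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to keep Monte-Carlo
error well below the asserted margins while remaining quick: 10,000
draws for distributional checks; 2,000 persons × 5 days for the
day-curve shape; 500 persons × 100 days for the 27-combination sweep
(both scenarios); 1,000 persons × 150 days × 6 configurations at 40
weekly hours for the workweek comparison; 20,000 observations for
logistic parameter recovery.

## Known limitations

* The comparative effect sizes (odds ratios, relative risks) are not
  calibrated to empirical epidemiology; only their direction and ordering
  are meaningful.
* Load accrual is concentrated at the morning peak but not entirely
  within the first two post-wake hours: because strain follows cortisol
  with recovery time-constant $1/\rho_R \approx 1.7$ h, the
  supra-threshold excess decays over several hours, and under the
  reference parameters the test suite measures roughly a third of total
  accrual inside the strict 2-hour window (the corresponding acceptance
  assertion documents this as a failing quantification of an otherwise
  reproduced qualitative pattern — the accrual mode sits at the morning
  peak itself).
* Night-before-free-day anticipation, health-behaviour routes to
  disease, multi-system allostatic indices and stressor-duration
  variation are out of scope.
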