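---
title: "Comorbidity-adjusted life expectancy by state-transition microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comorbidity-adjusted life expectancy by state-transition microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbsim)
```

## The problem

Clinical decisions for elderly men — whether to treat a localized cancer with
curative intent, whether a patient is eligible for a trial — often hinge on
expected remaining lifetime, not on age alone. Standard life tables ignore
comorbidity; comorbidity indices computed once at baseline ignore the fact
that comorbidity accumulates and drug use fluctuates over the years a
prediction is supposed to cover.

`morbsim` estimates population-level life expectancy for men aged 65–90 as a
function of three state variables: current age, the Charlson Comorbidity
Index (CCI, an integer score from hospital discharge diagnoses, cumulative
and hence never decreasing), and a Drug Comorbidity Index (DCI, computed from
prescriptions filled in the previous year, living on a 0.25 grid with floor
−0.75, able to rise and fall). Comorbidity is treated as a dynamic annual
process: transition models estimated from person-year register data drive a
per-individual microsimulation, and life expectancy is read off the simulated
survival curve.

## The annual cycle

One row of long-format data is one person-year: state at the start of the
year, outcome within it. One simulated year applies, in order:

1. if already dead, stop;
2. death draw — on death, record it and stop;
3. CCI-change draw; if a change occurs,
4. draw its size and add it (CCI only moves up);
5. DCI-change draw; if a change occurs,
6. draw its direction; on increase, draw the increase size;
7. on decrease, draw the decrease size (floored at DCI = −0.75);
8. age + 1, repeat until death or age 105.

No one survives past age 105: a man starting a year at the cap is terminated,
and the survival curve reaches zero at that anniversary plus one. All draws
in a year use start-of-year covariates, so the CCI block (steps 3–4) and the
DCI block (steps 5–7) commute; with the named RNG sub-streams described
below, they commute *bit-exactly*, which the test suite asserts rather than
assumes.

## The transition models

**Death.** A person-year ("life table") logistic model. The linear predictor
is

$$\eta = \beta_0 + \beta_a\,\text{age} + \beta_c\,g(\text{CCI};7)
 + \beta_d\,g(\text{DCI};14)
 + \gamma_c\,g(\text{age};100)\,g(\text{CCI};7)
 + \gamma_d\,g(\text{age};100)\,g(\text{DCI};14),$$

where $g(x;c) = (\min(x,c)-c)^2$ is the *quadratic-constant spline* (QCS): a
half-parabola with extremum at the cut point, constant (zero) above it, with
a continuous first derivative at the join. It encodes two empirical facts:
a one-unit comorbidity change matters more at low index values than at high
ones (curvature below the cut), and beyond some level extra comorbidity adds
nothing (constant above). Cut points are fixed configuration, not estimated:
7 for CCI, 14 for DCI, 100 years for the age interaction. Because $g$
*decreases* in $x$, a harmful covariate carries a **negative** weight on its
QCS term — a sign convention worth remembering when reading coefficients.
The age-QCS interaction makes the comorbidity effect attenuate with age and
removes the age-varying part entirely from 100 on. We chose
$(\min(x,c)-c)^2$ as the unique one-parameter second-degree form with these
properties; any scale or intercept it might carry is absorbed by the GLM
coefficients. A linear age main effect accompanies the interaction terms;
the six-term predictor is the minimal design realizing every property the
model is required to have, and the cut points are arguments, so a different
design can be dropped in.

**CCI change.** Two steps on categorized covariates (defaults: CCI
$\{0, 1, 2, \ge 3\}$, DCI $\{\le 0, (0,1], (1,3], >3\}$, age
$\{65\text{–}74, 75\text{–}84, \ge 85\}$ — all configurable through
`covariate_categorizer()`): a logistic occurrence model, then a size equal
to $1 + \text{Poisson}(e^\eta)$ fitted as two Poisson regressions stratified
by current CCI $= 0$ versus $> 0$. The $1+$ offset is forced by the
occurrence step: given that a change happened, its size cannot be zero. The
stratification by current CCI level is the natural two-model split for a
cumulative index; the split variable is a design choice, not an estimate.

**DCI change.** Four steps: logistic occurrence, logistic direction
(increase versus decrease, given change), and a Gamma model with log link
for the size of each direction. A raw Gamma draw is rounded to the nearest
0.25 with a minimum step of 0.25; a decrease is truncated so DCI never falls
below −0.75.

### Estimation at the DCI floor and on the grid

Two features of the DCI process need care at estimation time, and both were
found to matter empirically (biases of many standard errors at register
scale) rather than being theoretical niceties:

* **Floor rows.** A person-year starting at DCI $=-0.75$ cannot show a
  decrease — a drawn decrease truncates to a zero step and the row looks
  unchanged. Such rows would contaminate the occurrence and direction fits,
  so they are excluded from all four DCI fits. At simulation time the floor
  is simply enforced.
* **Grid likelihood.** Observed step sizes are Gamma draws *after* rounding
  to a 0.25 grid, a minimum of 0.25, and (for decreases) capping at
  `dci + 0.75`. With mean steps around 0.7, the grid cell is a third of the
  mean, and a continuous-density Gamma likelihood is visibly biased. Both
  size models are therefore fitted by maximum likelihood on the grid: an
  uncensored step $y$ contributes the Gamma probability of its rounding
  cell $[y-0.125, y+0.125)$ (widened to $[0, 0.375)$ at the grid minimum), a
  decrease recorded at its cap contributes the upper tail beyond
  $\text{cap}-0.125$, and a cap at the grid minimum captures every draw and
  contributes probability one. Shape and mean coefficients are estimated
  jointly; standard errors come from the observed information.

### Censoring semantics

Follow-up ends at death, emigration, or the administrative cut (maximum 11
years). The package treats vital status as observed for the whole of the
final year — as it is when deaths come from a national death register — while
censoring means the *next-year comorbidity measurement* is missing. A
censored row therefore carries a genuinely observed `died = 0` and
contributes to the death model, but not to the change models (its `cci_next`
and `dci_next` are absent). The alternative convention (censoring decided
before the death outcome is seen) silently records unobserved outcomes as
non-deaths and measurably biases the mortality fit downward; the package's
generator and fitters are consistent about the convention above.

## The microsimulation

For each start state, `n_individuals` identical men (default 10,000, the
reference design) are advanced through the annual cycle until death or age
105. The survival curve is the fraction alive at each anniversary; life
expectancy is its area. The default quadrature is the trapezoid on annual
knots — equivalently, half a year of credit in the year of death, the
standard actuarial reading of "area under the curve" — with a step-function
rule available (`quadrature = "step"`) since the choice is not forced by the
method; the option is recorded in the life-table output.

**Randomness** is organized in named sub-streams (`mortality`, `cci`, `dci`,
plus `entry`/`censor` in the generator), each an independent generator state
keyed by the master seed and, for grid runs, the start state. Every block of
a simulated year draws a fixed number of variates from its own stream,
computed from start-of-year covariates only, so (a) grid combinations are
independent and reproducible in any execution order, and (b) the step-order
invariance of the algorithm holds bit-exactly, not merely in distribution.

**The exact oracle.** When the size distributions are degenerate (CCI
increment fixed at 1, DCI step at ±0.25 — `size_fixed` / `step_fixed`), the
process is a finite Markov chain over (age, CCI, DCI), and
`exact_survival_oracle()` propagates the state distribution exactly. The
Monte-Carlo engine is validated against it at every anniversary. The
comparison uses a 3-standard-error band where the expected survivor count
supports the normal approximation (at least 5), and an exact binomial
envelope of the same nominal coverage (99.73%) in the deep tail, where
$\sqrt{S(1-S)/n}$ degenerates to a bound even a perfect simulator would
violate with probability $\approx nS$.

## The synthetic cohort generator

No register extract ships with the package; `generate_cohort()` emulates the
*structure* of one from known ground truth: entry ages 65–90 (mildly
decreasing weights), an age-shifted entry CCI distribution (prevalence of
CCI $=0$ falling linearly from 80% at 65 to 45% at 90, remainder geometric),
entry DCI on the grid with the non-positive share shrinking with age (30% at
65 to 15% at 90, positive values decaying exponentially with mean scale
1.2), six exchangeable region labels, a 2% annual emigration-style censoring
hazard, and an 11-year administrative cap. These defaults are fixed,
qualitative calibrations to the entry gradients reported for the Swedish
register population this design emulates; they are not fitted to any data
and the generator makes no attempt to reproduce register-specific numbers.

Individuals evolve under the ground-truth models *via the same update engine
as the microsimulation*, which is what makes the central round-trip
guarantee meaningful: fitting on a generated cohort recovers the generating
parameters within Monte-Carlo error, and every validation procedure closes
on cohorts generated from a fitted model's own parameters.

What passing these tests shows — and what it does not: the estimation and
simulation machinery is self-consistent and unbiased *under the model*. Real
register data violate the model in known ways (no duration dependence: a DCI
of 2 that just fell from 10 is treated like a DCI of 2 stable for years; no
calendar trends; no accident/violence mortality channel for the youngest,
longest-lived men), so agreement here does not certify accuracy on real
data, and individual-level clinical use would require validation beyond the
population level.

## The validation battery

Four procedures mirror how such a model is validated against register data,
where direct validation of life expectancy is impossible (it would need
40-year follow-up; registers offer 11):

* `observed_survival()` — product-limit (Kaplan–Meier) curves on annual
  follow-up, compared pointwise with simulated curves
  (`comparison_report()`), including restricted *years lost* over the first
  10 years (horizon minus trapezoidal area; years lost and restricted area
  always sum to the horizon).
* `mean_trajectories()` — observed versus simulated mean CCI and DCI among
  survivors per year of follow-up.
* `calibration()` — equal-frequency binned (default 10 bins; the count is
  configurable since no binning is canonical) predicted-versus-observed
  tables for the death and DCI-change models.
* `region_cross_validation()` — leave-one-region-out: fit on five regions,
  simulate from the held-out region's empirical entry states, compare with
  its Kaplan–Meier curve. The per-region simulation stream is keyed by the
  held-out entry-state content rather than the region label, so permuting
  labels permutes the reports unchanged.

## Numerical and design notes

* Probabilities from finite coefficients never reach 0 or 1; "forced"
  probabilities in tests use ±40 on the logit scale, exact at double
  precision.
* CCI is uncapped in simulation (the cut-7 QCS and the $\ge 3$ category make
  large values inert); DCI has no upper clamp for the same reason
  (cut 14).
* A CCI size stratum in which every change has size exactly 1 sits on the
  boundary of the Poisson model (log-mean $\to -\infty$); the fit warns and
  pins the increment rate at $e^{-40}$ instead of failing.
* Degenerate inputs fail loudly and specifically: single-level outcomes,
  empty direction strata, covariates outside fitted categories, malformed
  person-year rows (with row numbers), unknown configuration keys.
* Problem sizes used by the shipped checks were chosen to make Monte-Carlo
  bounds tight at desk scale: 10,000 men per cohort for simulation checks,
  ~200,000 person-years (30,000 men) for parameter recovery, 5,000 men per
  combination on a reduced 3 × 4 × 4 grid for the life-expectancy
  monotonicity check, and 12,000-man cohorts for the validation loop.

## Known limitations

The model is Markovian in (age, CCI, DCI): no duration dependence, no
history effects, and repeated DCI decreases in consecutive years are more
common in simulation than observed in registers. The Gamma size model mildly
underestimates large DCI changes on real data. Estimates are for men;
applying the machinery to women requires refitting. None of the real
register's numerical results are reproduced here — the package reproduces
the *method*, exercised end to end on synthetic cohorts.
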