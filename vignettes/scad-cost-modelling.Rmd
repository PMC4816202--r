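---
title: "Modelling long-term healthcare costs in stable coronary artery disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling long-term healthcare costs in stable coronary artery disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scadcost)
```

## The modelling problem

Patients with stable coronary artery disease (SCAD) — stable angina, or a
stabilised state six months after an acute coronary syndrome or coronary
intervention — accrue healthcare costs over decades, punctuated by
non-fatal myocardial infarctions and strokes that carry large acute and
persistent cost increments, and ended by cardiovascular (CVD) or
non-cardiovascular death. Decision makers need (i) descriptive first-year
and post-event cost summaries, (ii) covariate-level predictors of
first-year cost, and (iii) extrapolated 5-year and lifetime costs
stratified by baseline cardiovascular risk. `scadcost` implements that
full pipeline over three flat input tables (patient baseline, dated
events, 90-day period costs), together with a synthetic cohort generator
that emulates the linked electronic-health-record extracts such studies
draw on, which are access-controlled and cannot ship with software.

Everything runs on a common 90-day cycle grid; a model "year" is four
cycles (360 days), and calendar conversion uses 365.25 days per year.

## Cost categories

Each 90-day observation is split into components (inpatient, primary
care, diagnostics, drugs), from which three nested categories are
composed:

* **total** = all inpatient + primary care + diagnostics + all drugs;
* **CVD** = CVD-related inpatient + primary care + diagnostics +
  CVD-related drugs;
* **CHD** = CHD-related inpatient + primary care + diagnostics +
  CVD-related drugs.

CHD admissions are a subset of CVD admissions, so `chd <= cvd <= total`
row by row — an invariant `compose_cost_categories()` enforces. Share
statistics are ratios of means (`100 * mean(part) / mean(total)`),
rounded half-up to one decimal; this convention reproduces published
share figures exactly from published mean components. Outpatient costs
are out of scope (no linked outpatient data exists in the source
systems this emulates), so totals understate true NHS costs.

## Cohort rules

Cohort entry is the diagnosis date for stable angina and unspecified CHD,
and diagnosis + 182 days for an acute coronary syndrome. Six months is
fixed at 182 days so entry dates are reproducible across calendar
conventions. Two analysis windows are derived per patient: the first SCAD
year (cycles 1–4) and, for patients whose first event is non-fatal, the
first post-event year (the event cycle and the three following cycles).
A window interrupted by death is *complete* — decedents are retained and
their costs accrue to death — while a window cut short by any other
censoring (transfer out, administrative end) is excluded from summaries.

## First-year cost regression

Annual costs are positive and right-skewed, so covariate effects are
estimated with a gamma GLM with log link via `stats::glm`. Missing
biomarkers are handled by chained-equation multiple imputation
(`impute_cohort()`): predictive mean matching with five donors for
continuous variables, Bayesian logistic draws for binary flags, five
sweeps, M = 5 completed data sets, with the (log) outcome included as a
predictor so the imputation model is congenial with the analysis model.
No imputation package in the dependency set provides this, so it is
implemented in the package. Estimates are pooled by Rubin's rules:
pooled coefficient \(\bar Q\), within-imputation variance \(W\),
between-imputation variance \(B\), total \(T = W + (1 + 1/M)B\), with
normal-approximation intervals on the link scale.

Coefficients are reported as **natural-scale GBP increments** by
recycled predictions: the increment for a binary covariate is the cohort
average of (prediction with the covariate set) minus (prediction with it
unset); continuous covariates are shifted by one reporting unit. Whether
published forest plots use recycled or at-the-mean predictions is rarely
stated; recycled predictions were chosen because they average over the
observed covariate distribution rather than a synthetic mean patient.
Interval bounds use endpoint transformation (the same transform applied
at the coefficient's confidence limits), which respects positivity; the
difference from the delta method is second order. Zero-cost patients sit
outside the gamma support and are floored at GBP 0.01 (configurable);
with four cycles of primary-care and drug components a literal zero
annual total is rare in practice.

## 90-day panel cost model

Period costs follow an additive structure on the GBP scale:

\[
  c_{it} = \beta_0 + \beta_1 (t - 1) + x_i' \gamma
         + \sum_b \delta_b \, \mathbf{1}[\text{band}_b(it)]
         + \theta_d \, \mathbf{1}[\text{death}_d(it)] + \varepsilon_{it},
\]

with four 90-day bands after a non-fatal event (band 1 is the event
cycle) followed by a constant long-run increment, and one-off increments
in the cycle of CVD or non-CVD death. The additive GBP-scale form was
chosen because published 90-day estimates are expressed exactly this way
(a baseline cost, a per-period trend, additive event increments), and it
is fitted by pooled least squares with patient-clustered
(`sandwich::vcovCL`) standard errors. Only the first non-fatal event
carries increments; recurrent non-fatal events are out of scope. The
derived one-year incremental event cost is the sum of the four bands
(`event_year_cost()`). A linear-in-cycle trend is an explicit modelling
choice; age-driven alternatives cannot be distinguished from the
published figures.

## Multistate model and projection engine

The Markov structure has 18 states: Stable; for each non-fatal event
type (AMI, ischaemic stroke, haemorrhagic stroke) four one-cycle tunnel
states plus a long-run state, realizing the time-since-event cost bands
inside the chain; and two absorbing death states. Cause-specific
discrete-cycle hazards are competing exponential rates \(h_c\) per
cycle: the probability of leaving a state in a cycle is
\(1 - e^{-H}\) with \(H = \sum_c h_c\), allocated across causes in
proportion to \(h_c/H\). The same convention drives the synthetic
generator, the maximum-likelihood estimator (`fit_transitions()`), and
the projection engine, so estimator and engine share one discretization.
Covariate effects are proportional on the cause-specific hazards and
time-invariant; in particular **age does not advance during
extrapolation**. That follows the time-invariant-covariate design of the
panel model, but it matters greatly for lifetime numbers: young,
low-risk profiles keep their low death rates forever, so their modelled
life expectancy (and hence lifetime cost) is larger than an age-updating
model would produce. Events are timed at cycle end; a death still
accrues that cycle's background cost plus the death-cycle increment.

`run_trace()` propagates state occupancy deterministically;
`project()` sums expected per-cycle costs over cycles 1–20 (5 years) and
to the horizon (default 400 cycles, about 98.6 years; a warning reports
any residual survival mass above 1e-4). Five-year cardiovascular risk is
the probability that the first of AMI, stroke, or CVD death occurs
within 20 cycles, with non-CVD death as a competing risk. Life
expectancy is the sum of per-cycle survival times 90/365.25 years under
an end-of-cycle convention (certain death in cycle 1 gives zero).
Discounting uses 3.5% per annum with mid-cycle timing
\((k - 0.5) \cdot 90/365.25\) years — the standard health-economics
convention; end-of-cycle timing is available via `timing = "end"`. No
half-cycle correction is applied to cost accrual itself because the
90-day panel already discretizes accrual. `microsimulate()` samples
individual trajectories from the same transition probabilities and mean
cost structure and is the package's independent oracle: trace and
microsimulation agree within Monte Carlo error in the test suite.

## Risk deciles and reporting

Patients are ranked by modelled five-year risk and split into ten groups
of near-equal size (ties broken by patient id). Each decile is
represented by one covariate profile: means for continuous covariates
and prevalences — fractional values — for binary flags, which preserves
the decile-average linear predictor better than modal values (a modal
option would be a one-line change in `representative_profile()`).
`build_table3()` reports, per decile, risk (2 dp), mean age, life
expectancy, and 5-year/lifetime total/CVD/CHD costs, discounted and
undiscounted (GBP, nearest pound), with CHD/total and CVD/total shares
(1 dp). `cost_curves()` emits the per-cycle cumulative cost and survival
data behind cost-over-time figures, and `export_outputs()` writes all
tables atomically so identical configurations yield byte-identical
files.

## The synthetic cohort generator

`sim_config()` bundles the generator's ground truth. Defaults encode the
cohort structure reported for UK SCAD populations: 44% female; mean age
67 (men) / 72 (women), SD 12, truncated to 45–92 years; diagnosis mix
47.4% stable angina, 13.5% unstable angina, 6.7% STEMI, 9.7% NSTEMI,
22.6% other CHD (the published percentages sum to 99.9% and are
renormalized). Comorbidity prevalences follow logistic-in-age curves
(e.g. heart failure 8% at the age-67 reference with +0.7 log-odds per
decade) because comorbidity burden rises with age in real cohorts and
this is what makes background costs climb across risk deciles.

The ground-truth cost structure anchors on published 90-day estimates:
total-category baseline GBP 341 per cycle rising GBP 10 per cycle; an
AMI increment of GBP 5028 in the event cycle and GBP 521 per cycle long
run; death-cycle increments of GBP 2008 (CVD) and GBP 2240 (non-CVD).
Unprinted bands 2–4 are set so each event's four bands sum to the
published one-year incremental costs (AMI 7677, ischaemic stroke 8902,
haemorrhagic stroke 10477). Gamma noise has constant shape (default 0.5,
scale = mean/shape), the simplest right-skewed model consistent with a
gamma GLM; `gamma_shape = Inf` gives noise-free costs for exactness
tests. Components are drawn as independent gammas and recomposed so the
category nesting holds row by row; the additive structure must keep
every component mean non-negative, and a configuration that violates
this is rejected with an error rather than silently truncated.

Transition hazard defaults were calibrated analytically so that across
the cohort's age span the modelled five-year risk runs from a few
percent in the youngest decile to above forty percent in the oldest,
with non-CVD death dominating at younger ages — the gradient structure
reported for SCAD populations. This requires steeper age effects on CVD
transitions (0.95 per decade on the log hazard) than on non-CVD death
(0.55 per decade). Censoring is an independent per-cycle Bernoulli
(default 0.5% per cycle) and biomarker missingness is missing completely
at random at placeholder rates (25–30%); published sources rarely state
their missingness mechanism, and MCAR suffices to exercise the
imputation machinery.

What the generator does **not** emulate: raw primary-care/hospital
record layouts and coding systems, tariff-based unit costing, informative
censoring, recurrent non-fatal events, seasonal or calendar-time cost
trends, and covariate drift over follow-up. Passing tests therefore
demonstrate that the estimators recover the data-generating process they
assume — not that the assumed process is a complete description of real
EHR data.

## Numerical choices and problem sizes

* Transition ML uses `optim` (L-BFGS-B) with analytic gradients; baseline
  rates are bounded below at 1e-8 per cycle, so transitions with no
  observed events fall to the floor (with a warning when covariate
  effects are dropped).
* Occupancy row sums are maintained to 1e-10; probability rows to 1e-12.
* Predicted period costs are floored at zero with a warning; the
  additive model can otherwise go negative for extreme profiles.
* Deciles break risk ties by patient id, making assignment deterministic.
* The test suite sizes simulations so each estimator's sampling error is
  small relative to its effects: 100 000 draws for cohort composition
  checks, 50 000 for survival closed forms, 10 000 patients for panel
  recovery, 20 000 for transition recovery and the decile gradient, 50
  replicates of n = 5000 for imputation-pipeline coverage, and 200 000
  microsimulated trajectories against the trace. These are the package's
  validation sizes, chosen to keep Monte Carlo error well inside the
  assertion bands.

## Known limitations

* Time-invariant covariates: life expectancy for young profiles is
  optimistic (no ageing during extrapolation), which inflates their
  lifetime costs relative to an age-updating model.
* Point projections only: parameter uncertainty is quantified for the
  fits (cluster-robust and Rubin variances) but not propagated through
  the Markov engine (no probabilistic sensitivity analysis).
* Single non-fatal event: second and later non-fatal events neither
  change state nor add cost increments.
* The gamma GLM's log-linear mean is a working model for costs that the
  generator produces additively; recycled-prediction increments remain
  interpretable, but the two scales coincide only approximately.
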