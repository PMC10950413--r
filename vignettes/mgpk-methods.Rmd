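---
title: "Methods: concentration prediction, validation statistics and time-to-target analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concentration prediction, validation statistics and time-to-target analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgpk)
```

## Scope

`mgpk` evaluates how well an individualized two-compartment
pharmacokinetic model predicts serum magnesium during intravenous
magnesium sulfate treatment of preeclampsia, and how quickly treated
women reach the presumed therapeutic target of > 2.0 mmol/L.  It does
*not* estimate population PK parameters: the typical values and covariate
functions are inputs, applied as given.  Because patient-level clinical
data of this kind are access-restricted, the package carries a
first-class synthetic cohort generator so that every downstream stage is
exercised end-to-end without any external data.

## The disposition model

Amounts in the central (A1) and peripheral (A2) compartments follow

$$\dot A_1 = r(t) - (k_{10} + k_{12})A_1 + k_{21}A_2, \qquad
  \dot A_2 = k_{12}A_1 - k_{21}A_2,$$

with $k_{10} = CL/V_1$, $k_{12} = Q/V_1$, $k_{21} = Q/V_2$ and input rate
$r(t)$ in mmol/h.  Rather than integrating these ODEs per case, the
engine uses the closed-form biexponential response.  The hybrid
constants $\alpha > \beta > 0$ solve
$s^2 + (k_{10}+k_{12}+k_{21})s + k_{10}k_{21} = 0$; $\beta$ is computed
as $k_{10}k_{21}/\alpha$ to avoid cancellation.  A running unit-rate
infusion contributes

$$F(t) = \frac{1}{V_1}\left[\frac{A(1-e^{-\alpha t})}{\alpha}
  + \frac{B(1-e^{-\beta t})}{\beta}\right],\quad
  A = \frac{\alpha-k_{21}}{\alpha-\beta},\;
  B = \frac{k_{21}-\beta}{\alpha-\beta},$$

and linearity turns any dosing history into a superposition: a
maintenance segment of rate $r$ on $[t_0, t_1)$ contributes
$r\,[F(t-t_0) - F(t-t_1)]$, the second term switching on at $t_1$ and
producing the biexponential washout of a stopped segment.  A bolus is a
short infusion (default 20 min; the administration time is rarely
recorded, and an instantaneous mode with response
$G(t) = (Ae^{-\alpha t} + Be^{-\beta t})/V_1$ is available as the
duration-zero limit).  With $Q = 0$ the model degenerates to one
compartment and the engine switches to the corresponding limits;
`hybrid_constants()` refuses this case explicitly.

Two modelling conventions deserve emphasis:

* **Endogenous baseline.**  Pre-treatment magnesium is a flat additive
  constant, 0.74 mmol/L by default.  No turnover of the endogenous pool
  is modelled; the alternative (a baseline synthesis/elimination
  compartment) is indistinguishable at the data resolution treated here
  and would add parameters the validation cannot inform.
* **Dose units.**  Doses are labelled grams of magnesium sulfate;
  conversion to elemental millimoles is a configurable factor,
  4.06 mmol/g by default (heptahydrate, MgSO4·7H2O, 246.47 g/mol).  The
  salt form is often unstated on labels, so this is configuration, not a
  constant.

### Covariate individualization

Typical parameters are adjusted multiplicatively:
$CL = CL_{typ}\,(w/70)^{0.75}\,(cr/60)^{-1}$ and
$V_1, V_2 \propto (w/70)^{1}$, with $w$ body weight in kg and $cr$ serum
creatinine in µmol/L.  The allometric weight exponents are the standard
scaling choices; the inverse-creatinine term encodes renal elimination
of magnesium (higher filtration, faster clearance, lower concentration).
Evaluating at the reference covariates returns the typical values
exactly, which is asserted in the tests.  **The shipped typical values
(CL 4 L/h, V1 20 L, Q 2 L/h, V2 30 L) are a placeholder**: they give
magnesium-like behaviour — a distribution half-life of about two hours,
a slow half-life of about 17 h so a constant infusion approaches steady
state around 24–48 h, and a steady state of
$0.74 + 4.06\,r/CL \approx 1.76$ mmol/L at 1 g/h — but they are not the
published population estimates, which must be transcribed into the
config (`run_config()`, `config.yaml`) before any clinical-mimicking
run.

### Numerical conventions

* Time is hours everywhere internally; the prediction grid is uniform
  from 0 at 5-minute resolution (1/12 h) by default and includes the
  horizon when it falls on the grid (a tolerant floor guards against
  floating-point shortfall).
* Threshold crossing (`time_to_threshold()`) is evaluated on the grid
  with strict exceedance and no interpolation, for determinism; the
  returned time therefore upper-bounds the true crossing time by at most
  one grid step.
* Schedules are sorted with a deterministic tie-break (bolus before rate
  events at equal times); duplicate rate events at one time are refused
  as ambiguous.

## The synthetic cohort generator

The generator emulates a titrated-Zuspan treatment cohort:

* **Demographics** are independent log-normals parameterized by
  quartile triples, $\mu = \log(\text{median})$ and
  $\sigma = \log(q_3/q_1)/(2z_{0.75})$: weight (73, 84, 95) kg,
  creatinine (51, 57, 69) µmol/L, gestational age (33.1, 35.7, 38.4)
  weeks and treatment duration (23.7, 29.6, 46.0) h.  A two-parameter
  log-normal cannot match an asymmetric quartile triple exactly; the
  defaults reproduce each triple to within about 2 units, which the
  tests assert at n = 10 000.  Weight–creatinine correlation is zero by
  default (no joint structure is reported for such cohorts); a
  Gaussian-copula `copula_rho` is available.
* **Protocol.**  4 g bolus over 20 min with maintenance 1 g/h from time
  0; a check measurement 1 h after the start and after every rate
  change; if the *measured* value is below 2.0 mmol/L the rate increases
  by 0.25 g/h up to a cap of 1.5 g/h (two steps).  The cap keeps the
  time-weighted mean maintenance rate in the 1.0–1.5 g/h band typical of
  titrated cohorts; without it, hourly checks would drive nearly every
  case to an arbitrarily high rate within hours, which recorded cohorts
  do not show.  Titration only ever increases the rate.  The loop is
  closed: the same error-corrupted value that is recorded as the
  observation drives the titration decision.
* **Sampling** beyond the checks: routine samples at 4, 8, 12, 18, 24 h,
  every 12 h thereafter, and at the end of treatment (guaranteeing the
  two-measurement minimum of the inclusion rules).  Real sampling times
  are irregular; this regular template is an acknowledged
  simplification.
* **Measurement error**: 7% proportional CV plus 0.05 mmol/L additive
  SD — plausible assay error, config-exposed since no error magnitudes
  are reported for such measurements.  With probability 1% a reading is
  replaced by a spurious value drawn Uniform(3.5, 7.5) mmol/L,
  bracketing the kind of pre-analytical error (e.g. sampling from the
  infusion arm) that produces isolated implausible spikes.  Optional
  constant and weight-linear bias terms exist solely to test bias
  recovery.
* **Treatment duration** is drawn per subject from the log-normal above,
  truncated to [2 h, 60 h] and snapped to the 5-minute grid.
  Postpartum continuation is not modelled separately: delivery events
  are out of scope, and the empirical duration distribution already
  reflects them.

What passing tests on this generator do **not** show: robustness to
irregular real-world sampling times, EMR timestamp noise, model
misspecification (the generating model and the validated model share
structure), non-log-normal demographics, or informative censoring
(treatment stopped *because* of the measured level).  Zero-noise closure
and bias recovery demonstrate the statistical machinery is correct, not
that the placeholder parameters describe any real population.

## Validation statistics

* **Time matching** pairs each non-aberrant observation with the nearest
  grid point (offset at most 2.5 min); observations beyond the profile
  horizon are dropped with a warning.
* **Prediction error** is measured − predicted on the absolute
  concentration scale (mmol/L), *signed*: a negative mean means the
  model overestimates.  The 95% interval is Student-t over all pooled
  pairs; because cases contribute multiple pairs, a case-clustered
  variant (average within case first) is provided, as the handling of
  within-case correlation in comparable analyses is typically unstated.
* **Bias regressions** are ordinary least squares of the error on
  weight, creatinine or treatment duration with a two-sided t-test on
  the slope.  No multiplicity correction is applied.
* **Calibration** bins pairs into equal-width bins of predicted
  concentration (default 10) and reports mean measured value per bin.
* **Treatment periods** partition [0, 60] h as [0, 4), [4, 17),
  [17, 25), [25, 60]: the conventional bin labels "<4, 4–16, 17–25,
  25–60" leave 16–17 h unassigned and assign 25 h twice, so the
  half-open convention is a deliberate, documented choice.  Adjacent
  bins are compared by Welch t-tests on the maintenance rate in force at
  each sampling time and on the measured concentration.  A sample drawn
  exactly at the stop instant carries the rate running until then.
* **Aberrant-value screening** flags a reading when it exceeds
  3.5 mmol/L, sits more than 0.5 mmol/L above the last preceding
  unflagged value, and a later reading within 6 h returns to within
  0.5 mmol/L of that reference.  The "sits above the reference" guard is
  deliberate: without it a genuine sustained plateau just above
  3.5 mmol/L would be auto-flagged, although such a plateau is exactly
  the toxicity signal the screening must not hide.  The last observation
  of a series, and a high first observation (no reference), are never
  auto-flagged; they are listed for manual review.  Toxicity screening
  separately lists *every* reading above 3.5 mmol/L with a
  resolved-by-resample status.

## Time-to-target analysis

The event is the first non-aberrant *measured* concentration strictly
above 2.0 mmol/L — what an observer of the records could see, which
upper-bounds the true crossing time (a predicted-crossing mode exists
via `time_to_threshold()` for protocol-simulation studies).  Cases never
measured above target are censored at min(last observation, 25 h); the
horizon is configurable.  The Kaplan–Meier estimator, its Greenwood
variance on the log scale
($\widehat{Var}[\log S] = \sum d_j/(n_j(n_j-d_j))$, interval
$\exp(\log S \pm z\,se)$ clipped to [0, 1]) and the k-group log-rank
test (hypergeometric observed-minus-expected with the usual covariance,
generalized inverse on singular strata) are implemented from formulas;
the test suite cross-checks both against the `survival` package and
against hand-worked examples.  Quartile strata are rank-based with
deterministic tie-breaking by case id, so group sizes differ by at most
one even with tied covariate values.

## Problem sizes and runtimes

The test suite simulates cohorts of 10–56 cases for unit checks and 500
cases for the bias-recovery and quartile-direction properties;
engine–oracle agreement is checked on 100 random parameter/schedule
pairs against `deSolve` integration at tolerances of 1e-11, with
agreement required to 1e-6 mmol/L; the log-rank null calibration uses
1000 replicates of 60 subjects.  The whole suite runs in well under a
minute on a single CPU, and the full 56-case pipeline in about one
second.

## Known limitations

* The placeholder typical values and covariate forms are plausible, not
  estimated; every quantitative output of the demo pipeline inherits
  this.
* Between-subject PK variability is not simulated: individualized
  parameters are deterministic in the covariates, so the generator's
  prediction errors come from measurement noise alone.  This is the
  right condition for testing closure and bias recovery, but it
  understates real prediction error.
* The event analysis treats sampling times as exogenous.  In the
  titration loop they are not entirely (a below-target check schedules
  another check), which mildly couples sampling intensity to
  concentration level, as it does in practice.
* Log-rank power degrades under non-proportional hazards, which
  titration actively induces (low groups get dosed up); stratified
  contrasts should be read as descriptive.
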