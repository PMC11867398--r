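---
title: "Methods: a Markov cohort evaluation of lead screening and chelation in kidney transplant recipients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort evaluation of lead screening and chelation in kidney transplant recipients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leadcea)
```

`leadcea` implements an early economic evaluation of a screening-plus-
chelation programme for kidney transplant recipients (KTR) with high-normal
plasma lead. This vignette is the package's own account of the model: its
structure and assumptions, the parameters that matter and their defaults,
what the synthetic data generator does and does not emulate, the estimator
and numerical choices, and the known limitations.

## Disease model

Five states: functioning first graft (FG1), first graft failure on dialysis
(GF1), functioning second graft (FG2), second graft failure (GF2), Death
(absorbing). A cohort of 10,000 recipients enters at FG1 and is propagated
over 40 one-year cycles. Allowed transitions are FG1→{GF1, Death},
GF1→{FG2, GF2, Death}, FG2→{GF2, Death}, GF2→{Death}; GF1→FG2 is a
successful retransplantation and GF1→GF2 its immediate, persistent failure
(primary non-function, probability 0.007 per transplant). At most two
transplants are modelled — third transplants are rare enough to ignore.

Retransplantation from GF1 occurs with annual probability 0.15, constant to
age 65 and declining linearly to zero at age 80 (both ages configurable; the
cohort's age is `baseline_age + cycle`, default baseline 53). Because a
cohort model cannot carry individual ages, this single age clock is an
approximation shared by both arms.

Three time-to-event processes drive the cycle-specific transition
probabilities:

* **GF** (graft failure): lognormal, fitted *separately per lead tertile*
  (low/medium/high). The same series, re-indexed from the retransplantation
  cycle, governs the second graft — FG2 occupancy is book-kept as a tunnel
  by entry cycle so each second graft fails on its own clock. This clock
  reset mirrors transplant-vintage logic: a new graft starts its failure
  history afresh.
* **DWFG** (death with functioning graft) and **DwGF** (death after graft
  failure): gamma, fitted on the whole cohort and indexed on time since
  model start, because that is how they were estimated.

A survival curve `S` evaluated at integer years is converted to per-cycle
probabilities by `tp_i = 1 − S(i)/S(i−1)`. Two numerical conventions: the
conversion clamps to [0, 1], and if `S(i−1)` underflows to zero the tail
probability is set to 1 with a warning (the curve is exhausted; everyone
remaining transitions). Within a cycle, death is applied first and the
remaining transition probabilities are scaled by the cycle's survival, so
each row of the transition matrix sums to one exactly; with a single
competing event per state this proportional scaling is the least-informative
choice.

Half-cycle correction is trapezoidal: state-membership costs and QALYs are
valued at the mean of consecutive cycle-boundary occupancies. One-off event
costs (initial graft failure, transplantation, death) are counted at the
cycle of the event, uncorrected, which is standard trapezoidal practice.

## The intervention overlay

The programme screens every incident recipient at entry (blood draw + plasma
lead assay, €65.63 in total), treats those whose lead exceeds 0.38 µg/L —
the high tertile — with one course of oral DMSA (€570.95), monitors at the
start of year 2 (blood test; 60% receive a repeated course), and re-screens
surviving initially-eligible members for re-exposure every 5 years starting
5 years after treatment, retreating the 10% found re-exposed. Treated
recipients use medium-group graft-failure probabilities from the
effect-onset cycle (default cycle 2: chelation and its monitoring occupy
year 1; configurable). Re-exposed members are assumed detected and retreated
within the screening year, so they never revert to high-group probabilities —
only costs change. No adverse events are modelled; optional safety measures
(iron status, AST/ALT, an 8-week iron supplementation episode) add per-course
costs only.

Interpretation choices in the 26-row scenario table: the "time" column is
read as the delay from treatment to the first re-exposure screening and the
"repeated" column as the screening interval thereafter, which reproduces the
base case (first screen in year 6, then every 5 years) and the no-re-exposure
pattern (scenario 25) consistently. The 160%–460% entries printed in the
year-2 repeated-course column of the horizon/discounting scenarios are
treated as typographical artifacts of 60%, since those scenarios vary only
horizon and discounting. Repeated and re-exposure courses are costed like
first-year extra courses: one DMSA course plus one monitoring blood test
(draw + lead assay — whether the monitoring test includes the lead assay fee
is itemised nowhere, so the default includes it; both are configurable).
The iron-supplement unit cost is read as the price of one supplementation
episode, charged once per administered course when enabled.

## Economic inputs

Costs (EUR 2022, discounted at 4%/yr, cycle 1 undiscounted with factor
`(1+r)^−(t−1)`): annual transplant upkeep €14,376.98; dialysis as a
modality-weighted annual cost (80% centre HD, 4% home HD, 8% APD, 8% CAPD →
€111,137.41); one-off costs of €2,818.80 at graft failure, €103,993.68 at
retransplantation and €1,392.03 at death. Programme costs as above.
Productivity losses follow the friction-cost method (85-day friction period,
8-hour days, sex-mixed wage of €28.45/€24.70 with a configurable 60% male
mix): an employment-share drop at graft failure, hospital days (living/
deceased donor mix 50/50 by default) at retransplantation, and a
friction-period loss for deaths below 65 — the friction method prices paid
work, so deaths at or beyond retirement age carry no loss. Ages below 45 use
the 45–54 employment shares. QALYs use 0.81 with a functioning graft and the
HD/PD-weighted 0.84×0.56 + 0.16×0.58 = 0.5632 on dialysis (the utility-side
84/16 split is deliberately kept separate from the cost-side modality mix,
exactly as the source inputs print them), discounted at 1.5%/yr. The payer
perspective simply drops productivity losses.

## Synthetic cohort generator and default survival parameters

The generator (`cohort_spec()`, `simulate_cohort()`) emulates a single-centre
cohort of 670 recipients: plasma lead lognormal with median 0.31 µg/L and
IQR 0.22–0.45 (meanlog = log median; sdlog from the quartile-ratio probit
relation, ≈ 0.53), trichotomised at the 33.3rd percentile and 0.38 µg/L;
per-tertile lognormal graft-failure times; cohort-level gamma death times;
administrative censoring at 10 years (recruitment-to-follow-up span), with
no loss-to-follow-up process. The three endpoint times are drawn
independently per patient because the survival models are fitted per
endpoint; any competing-risk correlation is therefore absent from the
synthetic data. Covariates (age, sex, vintage, eGFR, proteinuria) and
repeated lead measurements are not simulated, so covariate-adjusted fitting
is out of scope — the fitting stage is group-stratified and unadjusted.
Passing tests on this generator therefore demonstrates the pipeline's
correctness, not the clinical accuracy of any real-world estimate.

Real fitted parameters, when available, are supplied via the `survival`
block of a YAML configuration and bypass fitting entirely. In their absence
the package ships synthetic defaults, chosen once for epidemiological
plausibility and clearly labelled synthetic: lognormal parameters implying
ten-year death-censored graft-failure fractions of about 8%, 12% and 25% in
the low, medium and high lead tertiles (sdlog 1.4, a strongly right-skewed
failure-time distribution), DWFG gamma(1.6, 0.08) (~20-year mean), DwGF
gamma(1.3, 0.2) (~6.5-year mean, reflecting dialysis mortality), with
standard errors of the size a ~220-per-tertile cohort with few events would
produce. All headline numbers in this package are conditional on these
synthetic inputs.

## Survival fitting and model selection

`fit_parametric()` fits right-censored exponential, Weibull, Gompertz,
gamma, lognormal, log-logistic and generalized-gamma models by maximum
likelihood (via `flexsurv`), with CIs from the observed information matrix.
Gamma is parameterised as (shape, rate) and the generalized gamma in the
three-parameter (mu, sigma, Q) form, which nests Weibull (Q = 1), lognormal
(Q = 0) and gamma (Q = sigma). `select_model()` ranks converged fits by AIC
(BIC alongside); because visual inspection and expert judgment are not
computable, an explicit override mechanism reproduces expert-informed picks
(lognormal for GF, gamma for both death endpoints) regardless of rank. A
Gompertz fit with negative shape can plateau above zero; extrapolation still
uses its closed form. Non-convergence warnings are captured on the fit
object as diagnostics and flagged fits rank after converged ones.

## Sensitivity analyses

**DSA.** Each registered parameter moves to the bounds of its 95% CI
(printed source ranges where available; otherwise mean ± 1.96 × a standard
error of 25% of the value), one at a time; the DMSA price gets an extra
half-to-double shock row. Parameters are ranked by output swing for the
tornado (top 15 shown by default).

**PSA.** All parameters vary jointly: beta for utilities and employment
shares, gamma for every cost, normal for counts, probabilities and the
survival parameters (from their 95% CIs). Hyperparameters are moment-matched
to the mean and the CI-implied variance; an infeasible match (beta variance
≥ m(1−m)) errors naming the parameter. Normal draws of probabilities are
clipped to [0, 1] and positive-support quantities floored at 10⁻⁶, with clip
counts recorded; counts are not rounded, as the cohort model is continuous.
Survival-parameter draws are independent — no covariance matrix between
parameters of one fit is available, which understates within-model
correlation and is a known limitation. Discount rates are varied in the DSA
only. Both arms run on the identical draw each iteration; a fixed seed
reproduces the sample bitwise.

## Value of information

EVPI is the two-option sample estimate `mean(max(INB, 0)) − max(mean(INB),
0)` on the incremental net benefit `INB = λΔE − ΔC`, divided by the
10,000-recipient cohort to give €/KTR (per-eligible-KTR values are three
times larger, as eligibility covers a third of the cohort). EVPPI uses the
single-loop nonparametric-regression estimator: INB is regressed on the
subset's draws with thin-plate spline smooths (`mgcv::gam`, basis dimension
k = 4 per parameter — small enough to stay stable at a few thousand PSA
iterations); the EVPPI is the value of knowing the fitted conditional mean.
EVSI simulates, per PSA iteration, a prospective follow-up study of n
recipients per group from that iteration's medium/high graft-failure
parameters (lognormal times, 10-year administrative censoring), reduces it
to per-group summary statistics (mean log observed time, event fraction),
and regresses INB on the summaries. Because censored event times inform
both meanlog and sdlog, EVSI is bounded by the EVPPI of *all* medium/high
graft-failure parameters, not the meanlogs alone; it is exactly zero at
n = 0 and non-decreasing in n up to Monte Carlo error.

## Budget impact

Five-year, healthcare-payer, dynamic national cohort: prevalence 12,068 and
incidence 957/yr, a third eligible. Year 1 screens prevalent plus incident
recipients; each later year adds incident entrants. Prevalent recipients are
not a single inception cohort, so by default they are distributed over
graft-age proportional to the standard-of-care alive-occupancy profile, and
the programme overlay starts at each stratum's current cycle (`start_cycle`);
costs per survivor at graft-age a are the inception cohort's cycle-(a+t)
costs divided by its alive fraction at a, which is exact by the Markov
property. A naive mode placing all prevalent recipients at model entry is
provided for comparison; both agree on sign and magnitude. Yearly totals are
discounted at the cost rate and the budget impact is the arm difference.

## Problem sizes and reproducibility

Every model run (10,000 recipients × 40 cycles, both arms) takes on the
order of 20–100 ms, so the deterministic analyses are interactive. The test
suite exercises the microsimulation oracle at 10⁶ patients, parameter
recovery at n = 2,000 per family, and a shared 500-iteration PSA; the
acceptance script uses a 4,000-iteration PSA and an EVSI grid up to n =
1,000 — sizes chosen to keep the full pipeline in the low minutes while
leaving Monte Carlo error well inside the tolerances asserted. A 10,000-
iteration PSA (`run_psa(n_iter = 10000)`) takes roughly 2–3 minutes. All
stochastic stages consume child seeds derived from one master seed, recorded
in the run manifest.

## Known limitations

* Cohort-level modelling cannot track individuals: recipients crossing the
  lead threshold over time are invisible, re-exposure affects costs but not
  (by assumption) transition probabilities, and a single age clock serves
  the whole cohort.
* Utilities are not age-adjusted; no adverse-event disutilities
  (assumption: none occur at this dosage).
* The synthetic generator omits covariates and competing-risk correlation;
  the default survival parameters are synthetic stand-ins, and every
  numerical result shown with them is illustrative of the method, not of any
  real cohort.
* PSA survival draws ignore within-fit parameter correlation.
* Whether dialysis upkeep applies to GF2 until death is assumed yes (graft
  failure implies dialysis unless dead).
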