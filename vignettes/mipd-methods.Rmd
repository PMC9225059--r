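---
title: "Bayesian forecasting of infliximab troughs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian forecasting of infliximab troughs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipdifx)
```

## The forecasting problem

Infliximab exposure during every-8-week maintenance therapy varies several
fold between patients, and troughs below about 5 µg/mL are associated with
loss of inflammatory control. A serum sample drawn mid-cycle — during the
linear terminal elimination phase, 3–4 weeks after the infusion — carries
enough information to forecast the end-of-cycle trough weeks before it
happens. `mipdifx` treats that as a Bayesian conditioning problem: a
population pharmacokinetic model supplies the prior, the patient's own
level(s) supply the likelihood, and every clinical quantity of interest is
a functional of the resulting conditional (posterior) distribution of the
individual parameters.

## Structural model

Disposition is a linear two-compartment model with zero-order infusion
input. Writing `k10 = Cl/V1`, `k12 = Q/V1`, `k21 = Q/V2`, the central
amount satisfies

$$\dot A_1 = \mathrm{in}(t) - (k_{10}+k_{12})A_1 + k_{21}A_2,\qquad
  \dot A_2 = k_{12}A_1 - k_{21}A_2,$$

and the concentration is `C = A1/V1` (mg and L give mg/L ≡ µg/mL, so no
unit conversions occur anywhere; times are in days). The production path
evaluates the closed-form biexponential solution: hybrid constants
`α, β` are the roots of `s² + (k10+k12+k21)s + k10 k21 = 0` (the smaller
root is computed as `αβ/α` via the product form to avoid cancellation),
per-event infusion/washout terms are superposed over the dosing history,
and linearity in dose holds exactly. `pk_ode_reference()` integrates the
same system numerically (deSolve, `lsoda`, piecewise between infusion
start/stop breakpoints, `rtol 1e-10` / `atol 1e-12`) and serves purely as
an independent oracle in the test suite: the closed form was chosen for the
sampler because it is two to three orders of magnitude cheaper per
likelihood evaluation than an ODE solve and exact rather than
tolerance-limited.

## Population prior and covariate model

The shipped prior (`inst/extdata/prior_default.yaml`) anchors the typical
values to reported cohort medians for this population — Cl 0.300 L/day,
V1 3.36 L, Q 0.134 L/day, V2 1.56 L — and uses conventional monoclonal
antibody population-PK structure for everything the source material names
but does not quantify:

| field | default | unit | rationale |
|---|---|---|---|
| `wt_exp_cl`, `wt_exp_q` | 0.75 | – | allometric scaling of clearances |
| `wt_exp_v1`, `wt_exp_v2` | 1.0 | – | volumes scale with body size |
| `ref_weight` | 70 | kg | adult reference |
| `alb_exp_cl` | −1.1 | – | low albumin tracks faster mAb catabolism |
| `ref_albumin` | 41.5 | g/L | mid-normal albumin |
| `ati_factor_cl` | 1.3 | fold | anti-drug antibodies accelerate clearance |
| `omega` | 0.30, 0.20, 0.30, 0.20 | log-SD | moderate IIV, larger on clearances |
| `sigma_prop` | 0.10 | – | proportional residual error |
| `loq` | 0.8 | µg/mL | assay lower limit |

The covariate form is a power model on ratios to the reference covariates,
so the typical values are recovered exactly at the reference patient. The
package's correctness is established by self-consistency
(simulate-then-recover under this prior), not by matching any particular
published parameter vector; every field is configuration-exposed, so a user
with access to a fitted population model can substitute its values
verbatim. An optional `omega_correlation` matrix supports correlated random
effects (e.g. Cl–V1); the default is independence. An `omega` entry of 0 is
treated as a point mass: the parameter stays at its covariate-typical value
in both prior sampling and MCMC, which is also how the test suite reduces
the sampler to one dimension for quadrature cross-checks.

Albumin and ATI status are held constant within a forecast: the tool
conditions on the mid-cycle visit, and cycle-scale covariate drift is far
smaller than the parameter uncertainty the posterior already carries.

## Likelihood and censoring

Quantified observations contribute a normal density with mean `f(t)` and
SD `0.10·f(t)`. Observations below the limit of quantitation contribute
`log Φ((0.8 − f(t))/(0.10·f(t)))` — the M3 censored-likelihood method — so
a BLQ result is informative (it pushes mass toward high clearance) rather
than discarded. Degenerate cases are defined, not special-cased away: a
model prediction of exactly zero is certain to be below the LOQ
(contribution 0) and impossible for a positive quantified value
(contribution −∞, returned rather than raised so the sampler simply
rejects). Values above the assay's upper range (34 µg/mL) are used as
recorded and flagged in the forecast output; only left-censoring is
modelled. Observation times are expressed as days after the most recent
infusion, matching how sampling times are recorded clinically, and are
mapped onto the absolute dosing timeline internally.

## Conditional sampling

The conditional distribution has no closed form, so `mipd_fit()` runs a
Metropolis–Hastings random walk on the log (random-effect) scale. Details
that the method leaves open were fixed as follows:

* joint Gaussian proposal shaped by the prior Cholesky factor, so one scale
  parameter governs all four dimensions;
* 500 burn-in iterations with the scale adapted every 50 iterations toward
  a 0.3 acceptance rate, then frozen (adaptation during burn-in only keeps
  the chain exactly Markovian afterwards);
* retained draws (default n = 100, the tool's operating choice; raise it
  for tighter Monte-Carlo error) are thinned so they span at least 5,000
  post-burn-in iterations — at n = 100 that is every 50th iteration;
* a single chain with a caller-supplied seed makes every fit, forecast and
  plot bit-reproducible;
* acceptance rates outside [0.05, 0.80] after adaptation produce a warning,
  never a failure — with a single observation the posterior is broad and
  the walk is robust.

With zero observations the likelihood is flat and the sampler targets the
prior itself; the test suite exploits this for a Kolmogorov–Smirnov check
against direct prior sampling, and cross-checks the one-dimensional case
against deterministic grid quadrature (2,001-point trapezoid on ±5 prior
SDs).

## Forecast summaries

Per-draw concentration functionals give: the day-56 trough (immediately
before the next scheduled infusion; the day is configurable), its median
and 80% prediction interval as the 10th/90th percentiles across draws
(type-7 quantiles, R's default), attainment probabilities as the fraction
of draws whose trough exceeds 5 or 10 µg/mL, and 10/25/50/75/90% profile
bands on a daily grid. Intervals describe parameter uncertainty in the
model-predicted concentration; residual assay noise is deliberately not
resampled into them (the interval is about the patient's true level, not
about a future measurement). `simulate()` adds residual noise when a
predictive distribution for a measurement is wanted.

`time_to_threshold()` finds, per draw, where the declining limb crosses a
threshold, by bisection to 0.01 day starting at the end of the last
infusion. Draws that never cross within the cycle are right-censored at the
cycle end and flagged; since a median over 100 draws is reported, up to
half the draws can be censored before the median itself saturates. An
`extrapolate` switch doubles the search horizon for draws still above the
threshold at day 56, for users who prefer extrapolated crossing times to
censoring.

## The synthetic cohort

`simulate_cohort()` reproduces the validation study design so that every
downstream stage is testable without patient data: 4 run-in q8w infusions
plus the observed cycle's dose at 5.9 mg/kg; weight log-normal with median
70 kg (σ_log 0.2) and albumin normal with mean 42.6 g/L (SD 2.9, truncated
at 20) — invented margins consistent with the reported cohort medians/IQRs;
ATI positivity with probability 0.15; one mid-cycle sample on an integer
day uniform in 26–30 and one end-of-cycle sample uniform in 44–56;
proportional noise and LOQ flagging applied to both. The true parameters
and the noise-free end-of-cycle concentration are carried alongside, and
`write_cohort()` keeps them in a separate `truth.csv` so forecaster inputs
can never leak them.

What passing tests on this cohort do show: the sampler is calibrated (80%
intervals cover the true end-of-cycle level for 70–90% of patients),
clearance is recoverable from a single mid-cycle level (Spearman ρ > 0.7),
and the full simulate → write → read → fit → forecast → Deming pipeline is
self-consistent (slope ≈ 1). What they cannot show: robustness to model
misspecification — real patients have time-varying clearance under
inflammatory burden, covariate measurement error, and assay behaviour the
proportional model only approximates. The synthetic cohort is generated
from the same model family the forecaster assumes, so these checks certify
the machinery, not the biology.

## Statistical validation module

The agreement statistics mirror standard method-comparison practice:

* **Deming regression** (errors-in-variables) with error-variance ratio
  λ = 1 by default — both axes are the same assay; λ is configurable. The
  slope CI is a leave-one-out jackknife (t-based on pseudo-values), a
  common choice where no analytic CI is assumed; R² is the squared Pearson
  correlation of the pairs. Fitting `(y, x)` returns the reciprocal slope
  exactly at λ = 1.
* **Cohen's kappa** with the large-sample standard error
  `√(p_o(1−p_o)/N)/(1−p_e)`; degenerate margins (chance agreement 1) define
  kappa as 0 with a warning.
* **2×2 diagnostics**: sensitivity, specificity, LR±, and the odds ratio
  with a Woolf log-normal CI; any zero cell triggers the Haldane–Anscombe
  +0.5 correction, flagged in the output.
* **ROC AUC** by the Mann–Whitney statistic (ties get half credit) with a
  DeLong placement-value CI, cross-checked in the tests against both
  exhaustive pair counting and an independent implementation (pROC).
* Dichotomization is strict: a value of exactly 5.0 µg/mL classifies
  negative.

## Problem sizes and numerical tolerances

The test and reproduction runs use: 100 random parameter sets for the
closed-form/ODE comparison (agreement demanded to 1e−6 relative; observed
≈ 3e−10); 2,000 draws for the prior-recovery KS check (distance < 0.1);
200 simulated patients for calibration and parameter recovery; 50 patients
for the end-to-end pipeline. These sizes hold Monte-Carlo error comfortably
below the widths of the acceptance bands while keeping a full run on one
CPU in minutes.

## Known limitations

* Elimination is strictly linear; target-mediated clearance at very low
  concentrations, subcutaneous administration and TNF-binding dynamics are
  out of scope.
* The residual-error model is applied to post-distribution samples, the
  only kind the intended workflow produces; behaviour for samples drawn
  during an infusion is untested territory.
* Maximum a posteriori estimation is deliberately not offered as a primary
  output — point estimates hide exactly the uncertainty the attainment
  probabilities exist to expose.
* The shipped prior is an anchor for self-consistent operation, not a
  substitute for a population model fitted to one's own assay and
  population.
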