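---
title: "Modelling 24-hour post-thrombolysis blood pressure trajectories"
author: "bptraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling 24-hour post-thrombolysis blood pressure trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bptraj)
```

## The problem

After intravenous thrombolysis with alteplase for acute ischaemic stroke,
blood pressure (BP) is monitored intensively for 24 hours: every 15 minutes
for 2 hours, every 30 minutes for the next 6 hours, then hourly — 37 readings
per channel (systolic and diastolic). Summarising such a series by a single
number (admission value, 24-h mean, SD) discards the *course* of BP, yet the
course — a slow drift down, a rapid stabilisation, persistent fluctuation at
a high level — carries prognostic information about early neurological
deterioration (END, an NIHSS worsening at 24 h), early neurological
improvement (ENI) and the 3-month functional outcome (modified Rankin Scale,
mRS; 0–2 favourable, 3–6 unfavourable).

`bptraj` implements the full analysis chain for this setting: a group-based
trajectory model (GBTM) identifying latent subgroups of patients sharing a
BP course, the adequacy and selection rules used to choose the number of
groups, the classic BP-variability parameters, logistic-regression
association of groups and parameters with binary outcomes, and a calibrated
synthetic cohort generator that makes the whole chain testable end to end.

## The trajectory model

For patient $i$ with readings $y_{it}$ at hours $t \in [0, 24]$, the model is
a $J$-component latent-class mixture. Conditional on membership in group
$j$, readings are independent censored-normal around a polynomial mean:

$$ y_{it} \mid (G_i = j) \sim \mathrm{CNORM}\!\left(\mu_j(t),\ \sigma^2\right),
   \qquad \mu_j(t) = \sum_{m=0}^{d_j} \beta_{jm} t^m , $$

where the CNORM density is normal in the interior of the scale bounds with
the tail mass accumulated at the bounds. Membership follows an
intercept-only multinomial logit, $\pi_j = e^{\theta_j} / \sum_k
e^{\theta_k}$ with $\theta_1 = 0$. The observed-data log-likelihood

$$ \ell = \sum_i \log \sum_j \pi_j \prod_t f\!\left(y_{it}; \mu_j(t),
   \sigma\right) $$

is maximised by EM. The E-step computes posterior membership probabilities
in the log domain (log-sum-exp); the M-step is, while censoring is inactive,
a set of posterior-weighted polynomial least-squares fits with a pooled
residual variance and $\pi_j$ equal to the posterior column means. With
active censoring bounds the M-step warm-starts at the weighted
least-squares solution and takes a short numerical ascent of the expected
complete-data log-likelihood, which keeps the observed likelihood monotone
(a generalised EM step).

Assumptions worth stating explicitly: a *common* residual SD across groups
(the standard default for this model family; per-group SDs are available via
`gbtm_control(group_sd = "group")`), independence of readings within patient
given the group, and raw uncentred hours as the time covariate — the
published per-group polynomial coefficients this package ships are only
meaningful on that scale. Censoring bounds default to $\pm\infty$: bedside
BP never sits on a scale bound, so the censoring terms are implemented and
unit-tested but inactive by default.

### Tunable parameters

| parameter | default | role |
|---|---|---|
| `orders` | 4 | polynomial degree per group (0–4). Quartic is the most flexible shape used for 24-h BP; published trajectory sets mix cubic and quartic groups. |
| `control$tol` | 1e-8 | relative log-likelihood convergence tolerance |
| `control$max_iter` | 500 | EM iteration cap per start |
| `control$n_starts` | 10 | EM starts: k-means on per-patient (mean, slope) features, a quantile slicing of per-patient mean level, then random hard partitions |
| `control$sigma_min` | 0.5 mmHg | floor on the residual SD, preventing degenerate likelihood spikes |
| `bounds` | ±Inf | CNORM censoring bounds (mmHg) |
| `seed` | — | required; all estimation randomness flows from it |

Group labels are permutation-invariant: after fitting, groups are relabelled
in ascending order of mean trajectory value over the observed time grid, so
"group 1" is always the lowest BP course. Modal-assignment ties break toward
the lowest label. BIC uses the number of *patients* as its sample size
(switchable to observations via `gbtm_control(bic_n = "observations")`); the
positive-form conventions are `aic = 2k - 2\ell` and `bic = k\log n - 2\ell`,
smaller is better, with $k = \sum_j (d_j + 1) + (J - 1) + 1$.

### Selection and adequacy

`gbtm_select()` fits candidate group counts (2–6 by default), screens each
fit with two adequacy rules — every group's modal share at least 5 %
(inclusive) and every group's average posterior probability of assignment
(APPA) strictly above 0.7 — and picks the adequate fit with the smallest
BIC. If nothing is adequate it returns the best-BIC fit flagged inadequate
rather than failing. Because the published trajectory sets mix cubic and
quartic groups without a stated rule, two shape policies are provided:
`"full"` keeps every group at the maximum degree, and `"prune"`
backward-drops each group's top term while its Wald $|z| < 1.96$, refitting
after each drop. Pruning with modest cohorts tends to settle on cubics: the
printed quartic coefficients are of order $10^{-3}$–$10^{-4}$ and are weakly
identified at $n \approx 353$.

## Classic BP parameters

`bp_parameters()` computes mean, max, min, range, sample SD (divisor
$n - 1$) and successive variation over a window. SV is implemented as the
root-mean-square successive difference,
$\sqrt{\sum_i (x_{i+1} - x_i)^2 / (m - 1)}$ over $m$ readings — the standard
"successive variation" of the BP-variability literature; a coefficient-style
variant normalised by the mean is available (`sv_cv = TRUE`), since the name
alone does not pin down the normalisation. Day and night windows are defined
by clock time with a configurable half-open day window defaulting to
[06:00, 22:00): the analysis literature rarely states its day/night
boundary, and this is the common ambulatory-monitoring convention. The
"immediately after thrombolysis" reading maps to the grid point nearest
$t = 1$ h — the end of the 1-hour alteplase infusion — with ties toward the
earlier reading.

## Outcome association

`trajectory_association()` fits three nested logistic models per outcome:
model 1 crude (group dummies against a configurable reference group), model
2 adding demographics (age, sex), model 3 adding every remaining covariate
that passes a univariate screen at $p < .1$. Inference is Wald throughout
(point OR $e^{\hat\beta}$, CI $e^{\hat\beta \pm 1.96\,\mathrm{se}}$),
matching the conventions of the clinical software this analysis style comes
from; no multiplicity adjustment is applied. Quasi-separated fits are
flagged `converged = FALSE` rather than reported silently. The reference
groups default to the moderate-stable courses (SBP group 3; DBP group 2).
For continuous BP parameters the OR is per mmHg by default with a per-SD
option — crude per-unit ORs on BP scales are small (≈1.02/mmHg) and the
per-SD scaling is often easier to read. `roc_auc()` computes the AUC as the
tie-corrected Mann–Whitney statistic with a Hanley–McNeil normal CI.

## The synthetic cohort generator

`simulate_bp_cohort()` inverts the generative model the estimator assumes,
calibrated to a published single-centre 353-patient post-thrombolysis
trajectory analysis whose printed group polynomials, group proportions,
outcome prevalences and crude odds ratios ship as the package defaults:

* five SBP groups (proportions 6.2/21.8/34.8/24.0/13.2 %) and four DBP
  groups (19.3/40.8/31.9/8.0 %), each a printed quartic/cubic polynomial;
* residual SDs of 8 (SBP) and 6 (DBP) mmHg — chosen once so the simulated
  within-group spread matches the gaps between adjacent printed trajectory
  bands, and configurable;
* iid Gaussian measurement noise by default; an index-based stationary AR(1)
  option (`noise = "ar1"`) is provided as a stress test, without claiming
  either matches real within-patient autocorrelation, which is unreported;
* covariates: age $\sim N(62.49, 11.79^2)$ years, 72.8 % male, glucose
  $\sim N(6.8, 3^2)$ mmol/L truncated at 2.5 (location from the cohort's
  descriptives; spread a field-typical choice), onset clock time uniform
  over 24 h;
* outcomes END (19.0 %), ENI (37.1 %) and unfavourable mRS (31.4 %) drawn
  from group-driven logistic models whose intercepts `calibrate_intercept()`
  solves to hit the marginal prevalence exactly (bisection to 1e-10); an
  optional per-mmol/L glucose effect enters centred at its mean so the
  calibration is preserved.

Outcomes are generated independently given covariates by default, although
END and ENI are clinically near-exclusive; `outcome_mode = "exclusive"`
draws them as a joint END / ENI / neither categorical (END keeps its
marginal, ENI shrinks slightly). Antihypertensive-treatment dynamics are
*not* mechanistically simulated: the fluctuating top groups' printed
polynomials already embody the resulting pattern. NIHSS score paths are not
simulated either; outcomes are binary labels.

What passing tests on these cohorts do and do not show: they demonstrate
that the estimation chain recovers the structure it assumes — correct group
count, shares within sampling error, odds ratios within Monte-Carlo error.
They do not validate the model against real bedside telemetry, which has
autocorrelated noise, treatment feedback (BP above 180/105 mmHg triggers
intravenous antihypertensives), missed readings, and joint SBP/DBP
dependence that the generator draws independently per channel.

## Numerical choices and degenerate inputs

* Log-domain posteriors throughout; an all-underflow row raises an
  estimation error instead of returning NaN.
* EM starts that collapse a group (posterior mass below one patient) are
  discarded; if every start collapses the fit errors with advice rather
  than returning a degenerate model.
* `sigma_min = 0.5` mmHg guards the noiseless-interpolation corner.
* Fits require every patient to have at least `max(orders) + 1` readings at
  distinct times; fewer raise a rank error up front.
* Convergence is relative: $|\Delta\ell| < 10^{-8}(|\ell| + 0.1)$.
* Reported JSON/CSV artifacts round floats to 1e-6 for reproducible diffs.

## Problem sizes used in the test suite

The suite exercises the published cohort size ($n = 353$, 37-point grid)
for structure recovery — 20 seeded replicates for the five-group SBP
selection frequency and the share/RMS recovery invariants, 5 replicates for
the DBP selection and classification-agreement checks — and large
outcome-only cohorts ($n$ = 50,000–200,000, series generation skipped) for
effect and prevalence recovery, where fitting noise would otherwise swamp
the calibration being checked. Null CI coverage uses 2000 replicates of
$n = 500$ to keep the Monte-Carlo error of the coverage estimate near half a
percentage point. These sizes are the package's own validation design.

## Known limitations

* Intercept-only membership: no covariates predict group membership.
* No dropout or missing-data model; series are assumed complete on the grid.
* Wald inference only; profile-likelihood CIs are not provided.
* The trajectory model treats within-patient residuals as independent;
  under AR(1) noise the group means remain unbiased but the likelihood is
  misspecified and BIC comparisons should be read with care.
* Ordinal (shift) analysis of the mRS is out of scope; the 3-month outcome
  enters only as the 0–2 / 3–6 dichotomy.

## A worked run

```{r, eval = FALSE}
library(bptraj)

coh <- simulate_bp_cohort(n = 353, seed = 1)
sbp <- coh$bp[coh$bp$channel == "SBP", ]

sel <- gbtm_select(value_mmhg ~ time_h | patient_id, sbp,
                   ngroups = 2:6, seed = 1)
sel
plot(sel$best, spaghetti = TRUE)

g <- sel$best$assignments[coh$outcomes$patient_id]
trajectory_association(g, coh$outcomes$end_24h, reference = 3,
                       covariates = coh$covariates[c("age", "sex", "glucose")])
roc_auc(g, coh$outcomes$end_24h)
```

`run_bp_pipeline()` performs the same chain end to end and writes every
artifact (trajectory coefficient tables, model JSON, BP parameter table,
association and AUC tables, a run report with the selection trace) to a
directory.
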