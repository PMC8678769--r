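# bptraj

Latent-group trajectory modelling of 24-hour blood pressure after
intravenous thrombolysis for acute ischaemic stroke.

After alteplase thrombolysis, blood pressure (BP) is monitored on a dense
24-hour schedule (every 15 min for 2 h, every 30 min for 6 h, then hourly —
37 readings per channel). How BP *moves* over those 24 hours — a slow drift
at a low level, a rapid stabilisation, persistent fluctuation at a very high
level — predicts early neurological deterioration (END), early neurological
improvement (ENI) and 3-month functional outcome (mRS). `bptraj` is for
stroke researchers and biostatisticians who want that trajectory analysis as
a reproducible, tested pipeline rather than a one-off statistical-software
run.

## The model

The core is a group-based trajectory model (GBTM): a `J`-component
latent-class mixture in which patient `i`'s readings are, conditional on
group `j`, independent censored-normal around a polynomial mean,

    y_it | G_i = j  ~  CNORM( mu_j(t), sigma^2 ),
    mu_j(t) = beta_j0 + beta_j1 t + ... + beta_jd t^d      (d <= 4),

with intercept-only multinomial-logit membership probabilities `pi_j`. The
observed-data likelihood `sum_i log sum_j pi_j L_ij` is maximised by EM
(log-domain posteriors, posterior-weighted polynomial least squares,
multiple seeded starts). Groups are relabelled by ascending mean trajectory,
so labels are initialisation-invariant. Model selection fits 2–6 groups,
requires every group to hold >= 5 % of patients and an average posterior
probability of assignment (APPA) > 0.7, and takes the adequate fit with the
smallest BIC (`bic = k log n - 2 logLik`, `n` = patients).

Around the core: classic BP-variability parameters (mean/max/min/range/SD
and successive variation, over 24 h and day/night clock windows), nested
logistic models (crude; + age, sex; + covariates screened at p < .1)
reporting odds ratios with 95 % Wald CIs, tie-corrected Mann–Whitney ROC
AUC with Hanley–McNeil intervals, and a synthetic cohort generator whose
shipped defaults are calibrated to a published 353-patient post-thrombolysis
trajectory set (five SBP and four DBP group polynomials, their proportions,
outcome prevalences and crude odds ratios).

## Worked example

```r
library(bptraj)

coh <- simulate_bp_cohort(n = 353, seed = 1)           # synthetic cohort
sbp <- coh$bp[coh$bp$channel == "SBP", ]

sel <- gbtm_select(value_mmhg ~ time_h | patient_id, sbp,
                   ngroups = 2:6, seed = 1)
sel
#> Trajectory-group selection over J = {2, 3, 4, 5, 6} (full shapes)
#>  J      orders   logLik  k      aic      bic min_share min_appa adequate
#>  2         4/4 -51253.2 12 102530.5 102576.9     0.275    1.000     TRUE
#>  3       4/4/4 -48281.9 18  96599.9  96669.5     0.275    1.000     TRUE
#>  4     4/4/4/4 -47203.8 24  94455.6  94548.4     0.113    1.000     TRUE
#>  5   4/4/4/4/4 -46205.1 30  92470.2  92586.2     0.059    1.000     TRUE
#>  6 4/4/4/4/4/4 -46200.1 36  92472.1  92611.3     0.059    0.737     TRUE
#> Selected J = 5 (adequate, smallest BIC)
```

The generating truth has five SBP groups; the selection trace shows BIC
bottoming out at `J = 5` (the six-group fit buys ~5 log-likelihood points
for six extra parameters, and its weakest group barely clears the APPA
rule). Associating the recovered groups with early neurological
deterioration, with the moderate group 3 as reference:

```r
g <- sel$best$assignments[coh$outcomes$patient_id]
trajectory_association(g, coh$outcomes$end_24h, reference = 3,
                       covariates = coh$covariates[c("age", "sex", "glucose")])
#>    model group        or    ci_low  ci_high          p converged
#> 1      1     1 0.7391304 0.2007736 2.721044 0.64940748      TRUE
#> 4      1     5 2.3879599 1.0819014 5.270677 0.03117423      TRUE
#> ...
roc_auc(g, coh$outcomes$end_24h)
#>        auc    ci_low   ci_high          p
#> 1 0.574313 0.4983397 0.6502862 0.05522121
```

At this cohort size the very-high fluctuating SBP group (group 5, generated
with a crude END odds ratio of 2.852) is estimated at OR 2.39 (95 % CI
1.08–5.27) in the crude model — the kind of attenuated-but-significant
estimate a 353-patient cohort yields — and group membership alone gives a
modest AUC of 0.57 for END. `run_bp_pipeline(out_dir, seed = 1)` runs the
same chain end to end and writes trajectory coefficient CSVs, model JSON,
the BP parameter table, association and AUC tables, and a run report.

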