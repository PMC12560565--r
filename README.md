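# psapredict

Individualized treatment-response prediction for four-arm psoriatic
arthritis (PsA) trials.

## The problem

In early PsA, DMARD-naive (DN) patients may start methotrexate or the JAK
inhibitor tofacitinib; patients failing a conventional synthetic DMARD
(DF) may add etanercept or tofacitinib. Response rates differ between
patients, and choosing the right drug first matters. Given a cohort of 80
patients (20 per arm) with baseline clinical measurements and the
Minimal Disease Activity (MDA) responder state at week 16 — at least 5 of
7 criteria met across joints, skin, pain, patient global, function and
entheses — this package answers: *can baseline data predict, per patient,
which available treatment has the higher probability of response, and how
well?*

## What it implements

For the binary responder outcome $y_i$ and baseline predictors $x_i$, all
models are penalized logistic regressions minimizing

$$\tfrac{1}{n}\textstyle\sum_i\big[\log(1+e^{\eta_i}) - y_i\eta_i\big]
 + \lambda\sum_j \gamma_j\big(\alpha|\beta_j| + \tfrac{1-\alpha}{2}\beta_j^2\big),$$

with the penalty $\lambda$ tuned by leave-one-out cross-validation at the
one-standard-error rule ($\lambda_{1se}$). On top of that core:

- **Cohort simulation** (`simulate_cohort`) with a known logistic outcome
  model, calibrated to a ~50% marginal MDA rate, so every stage is
  testable without trial data.
- **MDA outcome** (`compute_mda`, `compute_mda_with_fallback`) including
  the missed-visit rule combining week-16 patient-reported outcomes with
  a later examination.
- **Transformation screening** (`screen_transforms`): log / square-root
  candidates for skewed predictors, best univariable deviance wins.
- **Predictor selection** (`select_union`): elastic net ($\alpha=0.5$) in
  the full cohort and the tofacitinib / methotrexate / etanercept
  subgroups; the union of selected predictors is kept, with provenance.
- **Three treatment-effect strategies**: a homogeneous model (predictors
  + treatment dummies), a two-stage *risk model* (tofacitinib-only linear
  predictor, then treatment x LP interactions), and an *effect model*
  (elastic-net-selected predictor x treatment interactions). All Ridge at
  $\lambda_{1se}$.
- **Nested LOOCV evaluation** (`nested_loocv`): an outer leave-one-out
  loop reruns the entire recipe, an inner loop tunes $\lambda$; AUC-ROC
  over pooled held-out predictions (Mann-Whitney, ties 0.5).
- **Counterfactual impact** (`predict_counterfactuals`,
  `summarize_impact`): each patient's predicted response probability
  under tofacitinib versus their stratum comparator, and per-stratum
  summaries of the differences.

`tidy()`, `glance()`, `autoplot()`, `plot_roc()` and
`plot_counterfactuals()` cover inspection; `run_pipeline()` ties the
stages together and writes CSV/JSON/YAML artifacts.

## Worked example

```r
library(psapredict)

cohort <- simulate_cohort(cohort_config(), seed = 1)
mean(cohort$mda_week16)
#> [1] 0.4625

transforms <- screen_transforms(cohort, continuous_candidates())
sel <- select_union(cohort, default_candidates(), transforms = transforms)
sel$union
#> [1] "haq"

risk <- fit_risk_model(cohort, sel$union, transforms = transforms)
impact <- summarize_impact(predict_counterfactuals(risk, cohort))
impact
#> # A tibble: 2 x 8
#>   stratum     n  delta_min delta_max delta_median n_ties pct_favor_tofacitinib
#>   <chr>   <int>      <dbl>     <dbl>        <dbl>  <int>                 <dbl>
#> 1 DF         40 -0.000276  0.000271   -0.0000902       0                  32.5
#> 2 DN         40 -0.0000892 0.0000689  -0.00000233      0                  47.5
#> # i 1 more variable: pct_favor_comparator <dbl>
```

Read: in this simulated cohort 46% of patients reached MDA at week 16,
and elastic-net selection across the four fits retained only HAQ. The
cross-validated `lambda_1se` penalty then shrinks the risk model nearly
to the null, so the counterfactual probability differences are tiny
(hundredths of a percentage point) — the honest conclusion for this
draw is that little predictive signal survives regularisation at 20
patients per arm. Other seeds retain more signal and produce
percentage-point-scale differences; that sampling variability is exactly
what the simulation layer is for.

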