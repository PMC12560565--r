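---
title: "Predicting individualized treatment response in psoriatic arthritis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting individualized treatment response in psoriatic arthritis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Psoriatic arthritis (PsA) is heterogeneous, and so is its response to
disease-modifying treatment. In a four-arm randomized design,
DMARD-naive (DN) patients receive methotrexate or tofacitinib and
csDMARD-failure (DF) patients receive add-on etanercept or tofacitinib.
With roughly 20 patients per arm, the question is whether baseline clinical
measurements can predict, for an individual patient, which of the two
treatments available in their stratum has the higher probability of
response — response being Minimal Disease Activity (MDA) at week 16.

`psapredict` implements that analysis end to end: a synthetic cohort
generator with a known outcome model, the MDA responder definition,
transformation screening for skewed predictors, elastic-net predictor
selection across treatment subgroups, three Ridge-penalized
treatment-effect modelling strategies, nested leave-one-out
cross-validated (LOOCV) AUC-ROC evaluation, and per-patient
counterfactual treatment comparisons. Real trial cohorts of this design
are rarely public, so the generator is a first-class, tested module: every
downstream stage can be exercised against data whose generative truth is
known.

## The responder outcome

MDA is met when at least 5 of 7 criteria hold, with inclusive thresholds:
TJC68 $\le$ 1, SJC66 $\le$ 1, psoriasis BSA $\le$ 3%, pain VAS $\le$ 15 mm,
patient global VAS $\le$ 20 mm, HAQ $\le$ 0.5, and $\le$ 1 tender
entheseal point on the Leeds Enthesitis Index. `compute_mda()` evaluates
the checklist per patient; `compute_mda_with_fallback()` implements the
missed-visit rule in which week-16 patient-reported components (HAQ, pain
VAS, patient global VAS) are combined with examination components carried
back from the first subsequent visit, flagging such rows `mda_imputed`.
VAS thresholds assume millimetres on 0-100 scales; a 0-10 cm dialect can
be accommodated by rescaling the threshold vector.

## The synthetic cohort generator

`simulate_cohort()` draws `n_per_arm` patients per arm (default 20, the
trial's development-cohort size). Baseline covariates follow distribution
families chosen to look like an outpatient PsA population: lognormal CRP,
BSA and disease duration; shifted negative-binomial joint counts
respecting the eligibility floor of at least two tender and two swollen
joints; truncated-normal VAS scores with a latent correlation of 0.6
between the two patient-reported global scores; a scaled beta HAQ; and
binary flags. TNFi history is structurally zero in the DN stratum and has
probability 0.3 in DF; disease duration is short in DN (median 1 year)
and longer in DF (median 6 years). These defaults are modelling
assumptions, not published summary statistics, and every one of them is
overridable through `covariate_spec()`.

The outcome is exactly logistic:
$\operatorname{logit} P(\text{MDA}) = \beta_0 + \beta^\top x +
\tau_{\text{arm}} + \sum \gamma_{j,\text{arm}} x_j$.
The default coefficients give non-response effects to HAQ, LEI, TJC68 and
TNFi history, a protective effect to physician global VAS, and arm
effects $\tau$ of $0, 0, +0.56, -0.33$ (reference methotrexate/DN),
chosen so the marginal response rate is about 50% overall and about 60% /
40% in the etanercept and tofacitinib DF arms. The intercept (1.55) was
calibrated once by Monte Carlo against that 50% target. No
treatment-covariate interactions are present by default, and the implied
oracle discrimination (AUC of the true probabilities against realized
outcomes) is about 0.72, comparable to the cross-validated performance a
cohort of this kind can plausibly support.

Week-16 MDA components are generated from a latent improvement model —
baseline value times a treatment-response-dependent shrinkage factor plus
noise — and then deterministically adjusted so that the component-derived
MDA status equals the Bernoulli responder draw: the outcome model stays
exactly logistic while the component data remain internally consistent.
What the generator does *not* emulate: longitudinal visit schedules beyond
baseline and week 16, missing data (the analysis assumes complete
predictors), measurement error correlated across visits, and any
site/centre structure. Passing tests on simulated cohorts therefore
validate the *machinery*, not the clinical transportability of any fitted
model.

## Design matrix and transformation screening

For continuous predictors whose absolute sample skewness exceeds 1 (a
conventional rule of thumb; the threshold is an argument), univariable
logistic fits on the identity, natural-log and square-root scales are
compared and the lowest deviance wins — with one parameter per candidate
this is the AIC ordering. Variables with legitimate zeros use
$\log(x+1)$; negative-valued predictors keep the identity scale with a
warning. Continuous columns are standardized (mean 0, SD 1 on training
rows) because penalties are scale-sensitive; binary predictors and the
three treatment dummies (reference arm: methotrexate/DN) are left on
their natural 0/1 scale for interpretability. Whether to standardize at
all is exposed as an argument, since analyses of this kind do not always
state it. The standardization parameters are stored so new patients are
projected onto the identical scale.

## The penalized core

`fit_penalized()` minimizes

$$\frac{1}{n}\sum_i\left[\log(1+e^{\eta_i}) - y_i\eta_i\right]
  + \lambda\sum_j \gamma_j\left(\alpha|\beta_j| +
  \tfrac{1-\alpha}{2}\beta_j^2\right),$$

with unpenalized intercept and per-column penalty factors $\gamma_j$
(used to force main effects and treatment into a model while selecting
among interactions). The solver is iteratively reweighted least squares:
for $\alpha > 0$ the weighted subproblem is solved by coordinate descent
with soft thresholding and an active-set restriction, with the
unpenalized block (intercept plus any forced columns) updated by an exact
weighted least-squares solve between passes — plain coordinate iterations
crawl when forced columns are correlated; for Ridge ($\alpha = 0$) the
whole subproblem is solved exactly by a Cholesky factorization of the
$(p+1)$-dimensional system. Step halving onto the true objective makes
the iteration monotone. Convergence is declared at a relative objective
change below $10^{-7}$ (configurable), within $10^5$ iterations; IRLS
weights are floored at $10^{-6}$ to keep the subproblem well posed near
fitted probabilities of 0 or 1. The suite cross-checks solutions against
unpenalized `glm()` at vanishing $\lambda$ and against `glmnet` (with its
internal standardization disabled) at matched penalties.

The penalty grid holds 100 log-spaced values from $\lambda_{\max}$ (the
entry point of the first penalized coefficient, computed from the score
of the model containing only unpenalized columns) down to
$10^{-4}\lambda_{\max}$. Two numerical choices matter. First, the top of
the grid is inflated by a factor $1+10^{-6}$ so the path genuinely starts
at the null model instead of numerically straddling the soft-threshold
boundary — without this, "selection" at the largest penalty can report
coefficients of order $10^{-10}$. Second, for Ridge the usual convention
caps $\lambda_{\max}$ at the elastic-net entry point divided by $10^{-3}$;
since that cap sits three decades higher, the Ridge grid descends to
$10^{-7}\lambda_{\max}$ so that both mixings span a comparable range of
effective shrinkage.

`cv_path()` estimates, for every grid point, the cross-validated binomial
deviance by refitting the path from scratch on each training fold — a
brute-force leave-one-out loop is the definitional oracle and the
implementation matches it to $10^{-10}$. The standard error is taken
across per-observation held-out deviances. `lambda_min` minimizes the
mean; `lambda_1se`, the largest penalty within one standard error of that
minimum, is the choice used throughout the pipeline (the more regularised
model, appropriate at $n = 80$). At the trial size all cross-validation
is leave-one-out. For large simulated cohorts the `nfolds` argument
switches to K-fold with a deterministic, class-balanced fold assignment
(fold labels cycled within each outcome class), keeping every function
free of hidden randomness: given its inputs, every fit in this package is
reproducible without touching the RNG.

## Predictor selection

`select_union()` runs elastic-net selection (default mixing
$\alpha = 0.5$, halfway between the Ridge used for estimation and the
lasso; the mixing is an argument because analyses rarely state it) in
four fits: the full cohort with treatment dummies as penalized
covariates, the tofacitinib subgroup pooled across strata with a DN/DF
indicator, and the methotrexate and etanercept subgroups. A predictor is
selected when its coefficient is nonzero at `lambda_1se`; the union over
the four fits, with per-fit provenance, is the final predictor set.
Treatment and the stratum indicator are design variables and never count
as selected. Candidates constant within a subgroup (TNFi history among
DMARD-naive patients) are dropped from that fit only. An empty union is a
hard error directing the user to the CV paths, since every downstream
model needs at least one predictor.

## Three treatment-effect strategies

**Homogeneous** (`fit_homogeneous()`): Ridge logistic regression on the
selected predictors plus treatment dummies, penalty at LOOCV
`lambda_1se`. Treatment acts as a constant log-odds shift, yet the
*absolute* risk difference between treatments still varies across
patients — it peaks where the comparator probability is near one half —
so even this model can personalise.

**Risk modelling** (`fit_risk_model()`): stage 1 fits a Ridge model of
response on the selected predictors among tofacitinib-treated patients of
both strata, with a stratum indicator whose coefficient — like the
intercept — is excluded from the linear predictor
$\text{LP} = \hat\beta^\top x$ (stage-1 coefficients are mapped back to
the unstandardized analysis scale first, so a patient with all-zero
predictor values has LP exactly 0). Stage 2 then fits Ridge on the three
treatment dummies, the standardized LP, and the three LP-by-treatment
products, with its own cross-validated penalty; a flag provides an
unpenalized stage 2 instead. All predictive effects are thus modified by
treatment only through the single LP score — a deliberate data-reduction
device for small samples.

**Effect modelling** (`fit_effect_model()`): all predictor-by-arm
interaction columns (standardized predictor times non-reference-arm
dummy) are built, elastic net selects among the interactions while main
effects and treatment are exempt from the penalty (hierarchy is enforced
by construction), and the final model is refit by Ridge on mains,
treatment and the surviving interactions. With no interaction selected
the final model *is* the homogeneous model, computed through the
identical code path, and the suite asserts the predictions agree to
$10^{-6}$.

Treatment dummies are penalized along with the predictors by default in
all strategies — analyses of this kind do not state the convention, the
choice affects reported coefficients, and a `penalize_treatment = FALSE`
flag exposes the alternative. One consequence worth knowing: with
penalized dummies, refitting against a different reference arm would not
reproduce predictions exactly, because the Ridge penalty is not invariant
to reparameterisation; with the flag set the invariance is exact.

`predict_counterfactuals()` evaluates a fitted model twice per patient —
under the stratum-consistent tofacitinib arm and under the stratum
comparator (methotrexate for DN, etanercept for DF), holding covariates
and, for the risk model, the LP fixed. Cross-stratum counterfactuals are
refused. `summarize_impact()` reports per-stratum minimum, maximum and
median of the probability difference and the percentage of patients
favouring each treatment; exact ties (a measure-zero event) are labelled
`"tie"`, counted separately, and excluded from the percentages.

## Nested cross-validated evaluation

`nested_loocv()` leaves each patient out in turn, reruns the entire
fitting recipe on the remainder — for the risk model that includes
stage-1 refitting and LP recomputation — tunes the penalty by an inner
LOOCV at `lambda_1se`, and predicts the held-out patient under their own
arm. The AUC over the pooled held-out pairs (Mann-Whitney, ties 0.5) is
the outer performance estimate; the resubstitution AUC of the model tuned
on the full data is reported alongside as `auc_inner` and is
systematically optimistic. `final_lambda` is the `lambda_1se` of a
full-data inner-style LOOCV (the per-fold tuned penalties are also
returned), which resolves an ambiguity in how "the resulting nested
LOOCV $\lambda$" should be read; we record it as an assumption.

Predictor selection is by default performed once on the full data, before
the outer loop — matching the two-phase presentation of this kind of
analysis — which leaks some selection information into the outer
estimate. `reselect = TRUE` repeats the union selection inside every
outer fold for a fully honest estimate; both modes are first-class and
the difference between them is itself informative.

**A known limitation of pooled LOOCV AUC.** When the tuned model is at or
near the null model — as it is on pure-noise outcomes, where
`lambda_1se` rightly shrinks everything away — each held-out probability
reduces to the training-fold prevalence $(k - y_i)/(n-1)$, which is
strictly anti-monotone in the left-out patient's own outcome. Pooling
such predictions drives the AUC towards 0 rather than 0.5. This is a
documented pathology of combining leave-one-out probabilities into one
ranking statistic, not an implementation defect: the same procedure
applied to informative data (where coefficients, not the intercept,
dominate the ranking) behaves as expected. We deliberately do not
"correct" the held-out probabilities (e.g. by per-fold centring), because
that would break the elementary contract that a constant predictor scores
exactly 0.5 through ties; instead the behaviour is documented here and
asserted in the test suite as a property of the method. Interpret
near-zero outer AUCs at this sample size as "no usable signal survived
regularisation", not as anti-prediction.

## Problem sizes used by the tests

The suite exercises the trial design size ($n = 80$, LOOCV throughout)
for the end-to-end pipeline, and larger simulated cohorts (250 to 1000
patients per arm, 5 to 20 replicate seeds) for parameter-recovery,
selection-consistency and collapse properties, where 5- or 10-fold CV
replaces LOOCV — at those sizes the K-fold estimate is statistically
equivalent for tuning and the leave-one-out loop would be numerically
disproportionate. Tolerances on recovered coefficients (±0.15 to ±0.2)
are Monte-Carlo bands over the replicate seeds.

## Known limitations

- Baseline covariate distributions are plausible assumptions, not fitted
  to any published table; conclusions about *data* should never be drawn
  from the generator, only conclusions about the *pipeline*.
- The pooled-LOOCV AUC pessimism described above affects any near-null
  tuned model.
- The elastic-net mixing for selection and the treatment-penalization
  convention are defaults with flags, since the analyses this package
  emulates do not state them.
- Model export covers prediction exactly (JSON round trips reproduce
  probabilities to machine precision) but not the CV paths, which are
  recomputable.
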