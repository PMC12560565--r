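# shared fixture: default study conditions at a size where estimation is easy
big_cohort <- function(seed, n_per_arm = 500, ...) {
  simulate_cohort(cohort_config(n_per_arm = n_per_arm, ...), seed = seed)
}

test_that("homogeneous model recovers constant treatment effects", {
  arms <- c("arm_TOFA_DN", "arm_ETN_DF", "arm_TOFA_DF")
  est <- rowMeans(vapply(1:5, function(s) {
    co <- big_cohort(70 + s)
    m <- fit_homogeneous(co, true_predictors, lambda = 1e-6)
    m$fit$coefficients[arms]
  }, numeric(3)))
  truth <- cohort_config()$true_treatment_effects[-1]
  expect_lt(max(abs(est - truth)), 0.15)
})

test_that("treatment enters the homogeneous model as a pure log-odds shift", {
  co <- big_cohort(72, n_per_arm = 50)
  m <- fit_homogeneous(co, c("haq", "lei"), lambda = 0.05)
  two <- co[c(1, 1), ]
  two$arm <- c("MTX_DN", "TOFA_DN")
  eta <- unname(qlogis(predict_response(m, two)))
  expect_equal(eta[2] - eta[1],
               unname(m$fit$coefficients["arm_TOFA_DN"]),
               tolerance = 1e-10)
  # zero design row in the reference arm: probability is the intercept alone
  expect_equal(unname(predict(m$fit, matrix(0, 1, length(m$fit$coefficients),
                                            dimnames = list(NULL, names(m$fit$coefficients))),
                              type = "response")),
               plogis(m$fit$intercept), tolerance = 1e-12)
})

test_that("risk-model LP excludes intercept and stratum and is 0 at zero", {
  co <- big_cohort(73, n_per_arm = 50)
  m <- fit_risk_model(co, c("haq", "lei", "vas_physician_global"),
                      nfolds = 10)
  # a patient with all predictor values zero has LP exactly 0
  zero <- co[1, ]
  zero$haq <- 0; zero$lei <- 0L; zero$vas_physician_global <- 0
  expect_equal(linear_predictor(m, zero), 0)
  # shifting the stage-1 intercept never changes any LP
  shifted <- m
  shifted$stage1$intercept <- shifted$stage1$intercept + 5
  expect_identical(linear_predictor(shifted, co), linear_predictor(m, co))
  # stage 2 has exactly the 7 prescribed non-intercept columns
  expect_length(m$stage2$coefficients, 7L)
  expect_setequal(names(m$stage2$coefficients),
                  c("arm_TOFA_DN", "arm_ETN_DF", "arm_TOFA_DF", "lp",
                    "lp:arm_TOFA_DN", "lp:arm_ETN_DF", "lp:arm_TOFA_DF"))
})

test_that("zeroed LP-by-treatment terms collapse to constant arm contrasts", {
  co <- big_cohort(74, n_per_arm = 50)
  m <- fit_risk_model(co, c("haq", "lei"), nfolds = 10)
  m$stage2$coefficients[c("lp:arm_TOFA_DN", "lp:arm_ETN_DF",
                          "lp:arm_TOFA_DF")] <- 0
  dn <- co[co$stratum == "DN", ]
  contrast <- qlogis(predict_response(m, dn, arm = "TOFA_DN")) -
    qlogis(predict_response(m, dn, arm = "MTX_DN"))
  expect_lt(diff(range(contrast)), 1e-10)
})

test_that("stage 2 recovers a shared LP-by-treatment interaction", {
  # outcome depends on treatment only through an LP x treatment interaction
  # acting in the etanercept arm; tofacitinib arms are unmodified, so the
  # stage-1 model learns the LP and stage 2 must find the interaction
  g_etn <- 0.8
  cfg <- cohort_config(
    n_per_arm = 1000, true_intercept = 1.0, true_beta = c(haq = -0.9),
    true_treatment_effects = c(MTX_DN = 0, TOFA_DN = 0, ETN_DF = 0,
                               TOFA_DF = 0),
    true_interactions = list(
      list(predictor = "haq", arm = "ETN_DF", effect = g_etn * -0.9)))
  est <- vapply(1:5, function(s) {
    co <- simulate_cohort(cfg, seed = 800 + s)
    m <- fit_risk_model(co, "haq", lambda_stage1 = 1e-6,
                        lambda_stage2 = 1e-6)
    # generative stage-2 coefficient on the standardized LP scale
    m$stage2$coefficients[["lp:arm_ETN_DF"]] /
      m$stage2$coefficients[["lp"]] / g_etn
  }, numeric(1))
  # ratio of interaction to main LP slope recovers g within Monte-Carlo error
  expect_lt(abs(mean(est) - 1), 0.2)
})

test_that("effect model collapses to the homogeneous model without interactions", {
  co <- big_cohort(75, n_per_arm = 200)
  em <- fit_effect_model(co, true_predictors, nfolds = 10)
  expect_equal(nrow(em$selected_interactions), 0L)
  hm <- fit_homogeneous(co, true_predictors, nfolds = 10)
  p_e <- predict_response(em, co)
  p_h <- predict_response(hm, co)
  expect_lt(max(abs(p_e - p_h)), 1e-6)
})

test_that("a strong generative interaction is selected by the effect model", {
  cfg <- cohort_config(
    true_interactions = list(
      list(predictor = "haq", arm = "TOFA_DN", effect = -2),
      list(predictor = "haq", arm = "TOFA_DF", effect = -2)),
    n_per_arm = 1000)
  hits <- vapply(1:5, function(s) {
    co <- simulate_cohort(cfg, seed = 900 + s)
    em <- suppressWarnings(fit_effect_model(co, true_predictors, nfolds = 5))
    any(em$selected_interactions$predictor == "haq" &
          em$selected_interactions$arm %in% c("TOFA_DN", "TOFA_DF"))
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("interaction columns are never built for the reference arm", {
  co <- big_cohort(76, n_per_arm = 50)
  em <- fit_effect_model(co, c("haq", "lei"), nfolds = 10)
  expect_false(any(grepl("arm_MTX_DN", names(em$fit$coefficients))))
  x <- psapredict:::interaction_columns(em$design$x, c("haq", "lei"))
  expect_equal(ncol(x), 6L) # 2 predictors x 3 non-reference arms
})

test_that("counterfactual deltas keep one sign per stratum under homogeneity", {
  co <- big_cohort(77, n_per_arm = 100)
  m <- fit_homogeneous(co, true_predictors, lambda = 0.02)
  pairs <- predict_counterfactuals(m, co)
  for (st in c("DN", "DF")) {
    d <- pairs$delta[pairs$stratum == st]
    expect_true(all(d > 0) || all(d < 0), info = st)
  }
  # for a constant log-odds shift d, |delta| peaks at the comparator
  # probability plogis(-d / 2), which sits near 1/2 for small shifts
  for (st in c("DN", "DF")) {
    sub <- pairs[pairs$stratum == st, ]
    shift <- qlogis(sub$p_tofacitinib[1]) - qlogis(sub$p_comparator[1])
    peak_at <- plogis(-shift / 2)
    ord <- order(abs(sub$p_comparator - peak_at))
    expect_equal(unname(which.max(abs(sub$delta))), ord[1])
    expect_lt(cor(abs(sub$p_comparator - 0.5), abs(sub$delta)), 0)
  }
})

test_that("cross-stratum counterfactuals are refused", {
  co <- big_cohort(78, n_per_arm = 25)
  m <- fit_homogeneous(co, c("haq", "lei"), nfolds = 10)
  dn <- co[co$stratum == "DN", ]
  expect_error(predict_response(m, dn, arm = "ETN_DF"), "Cross-stratum")
})

test_that("impact summaries aggregate the counterfactual pairs faithfully", {
  co <- big_cohort(79, n_per_arm = 100)
  m <- fit_homogeneous(co, true_predictors, lambda = 0.02)
  pairs <- predict_counterfactuals(m, co)
  imp <- summarize_impact(pairs)
  for (st in c("DN", "DF")) {
    d <- pairs$delta[pairs$stratum == st]
    row <- imp[imp$stratum == st, ]
    expect_equal(row$delta_min, min(d))
    expect_equal(row$delta_max, max(d))
    expect_equal(row$delta_median, median(d))
  }
  # all-negative deltas in a stratum mean the comparator is favored by 100%
  df_row <- imp[imp$stratum == "DF", ]
  if (all(pairs$delta[pairs$stratum == "DF"] < 0)) {
    expect_equal(df_row$pct_favor_comparator, 100)
  }
  # exact ties are reported separately and excluded from the percentages
  m0 <- m
  m0$fit$coefficients[] <- 0
  tied <- summarize_impact(predict_counterfactuals(m0, co))
  expect_equal(tied$n_ties, c(200L, 200L), ignore_attr = TRUE)
  expect_equal(tied$pct_favor_tofacitinib, c(0, 0))
})

test_that("fitted strategy models survive a JSON round trip exactly", {
  co <- big_cohort(80, n_per_arm = 40)
  tr <- screen_transforms(co, continuous_candidates())
  models <- list(
    fit_homogeneous(co, c("haq", "bsa"), transforms = tr, nfolds = 10),
    fit_risk_model(co, c("haq", "bsa"), transforms = tr, nfolds = 10),
    fit_effect_model(co, c("haq", "bsa"), transforms = tr, nfolds = 10))
  for (m in models) {
    path <- withr::local_tempfile(fileext = ".json")
    export_model(m, path)
    m2 <- import_model(path)
    expect_equal(predict_response(m2, co), predict_response(m, co),
                 tolerance = 1e-12)
    pairs <- predict_counterfactuals(m, co)
    pairs2 <- predict_counterfactuals(m2, co)
    expect_equal(pairs2$delta, pairs$delta, tolerance = 1e-12)
  }
})
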