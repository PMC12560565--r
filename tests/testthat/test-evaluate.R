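test_that("AUC equals the pairwise concordance enumeration", {
  expect_equal(auc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(auc(c(0.5, 0.5), c(1, 0)), 0.5)
  withr::with_seed(31, {
    # duplicated probabilities exercise the tie convention
    p <- round(runif(200), 1)
    y <- rbinom(200, 1, 0.4)
  })
  expect_lt(abs(auc(p, y) - auc_oracle(p, y)), 1e-12)
  # constant predictor: every pair is a tie
  expect_equal(auc(rep(0.3, 50), rep(c(0, 1), 25)), 0.5)
  expect_error(auc(p, rep(1, 200)), "classes")
})

test_that("AUC is invariant under strictly monotone transforms", {
  withr::with_seed(32, {
    p <- runif(100)
    y <- rbinom(100, 1, p)
  })
  a <- auc(p, y)
  expect_equal(auc(qlogis(p), y), a)
  expect_equal(auc(p^3, y), a)
  expect_equal(auc(1 - p, y), 1 - a)
})

test_that("ROC points are monotone and integrate back to the AUC", {
  withr::with_seed(33, {
    p <- round(runif(300), 2)
    y <- rbinom(300, 1, plogis(3 * (p - 0.5)))
  })
  roc <- roc_curve(p, y)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_lt(abs(psapredict:::trapezoid_area(roc$fpr, roc$tpr) - auc(p, y)),
            1e-12)
  # a perfect classifier passes through (0, 1)
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
})

test_that("separable data achieves outer AUC 1 under nested evaluation", {
  n <- 40
  co <- withr::with_seed(34, {
    x <- c(rnorm(n / 2, -3, 0.3), rnorm(n / 2, 3, 0.3))
    tibble::tibble(
      patient_id = sprintf("P%02d", 1:n),
      arm = rep(c("MTX_DN", "TOFA_DN", "ETN_DF", "TOFA_DF"), n / 4),
      stratum = ifelse(arm %in% c("MTX_DN", "TOFA_DN"), "DN", "DF"),
      x1 = x, mda_week16 = as.integer(x > 0))
  })
  e <- nested_loocv(co, "homogeneous", "x1", fixed_lambda = 1e-3)
  expect_equal(e$auc_outer, 1)
})

test_that("fixing the penalty reduces nested CV to plain leave-one-out", {
  co <- noise_cohort(24, p = 2, seed = 35)
  co$mda_week16 <- withr::with_seed(36,
    rbinom(24, 1, plogis(co$x1)))
  lam <- 0.05
  e <- nested_loocv(co, "homogeneous", c("x1", "x2"), fixed_lambda = lam)
  # hand-rolled plain LOOCV at the same fixed penalty
  manual <- vapply(seq_len(nrow(co)), function(i) {
    m <- fit_homogeneous(co[-i, ], c("x1", "x2"), lambda = lam)
    predict_response(m, co[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(e$held_out$probability, unname(manual), tolerance = 1e-12)
  expect_equal(e$auc_outer, auc(manual, co$mda_week16))
})

test_that("tuned-model resubstitution AUC is optimistic on noise", {
  co <- noise_cohort(60, p = 3, seed = 37)
  e <- suppressWarnings(nested_loocv(co, "homogeneous", c("x1", "x2", "x3")))
  expect_gt(e$auc_inner, e$auc_outer)
  expect_equal(nrow(e$held_out), 60L)
  expect_true(all(!is.na(e$held_out$probability)))
  g <- glance(e)
  expect_equal(g$n_skipped_folds, 0L)
  expect_equal(g$final_lambda, e$final_lambda)
})

test_that("the nested evaluator reruns the whole recipe per outer fold", {
  co <- simulate_cohort(cohort_config(n_per_arm = 10), seed = 38)
  e <- suppressWarnings(
    nested_loocv(co, "risk", c("haq", "lei"), nfolds_inner = 10))
  # every outer fold tuned its own penalty; lambdas differ across folds
  expect_equal(length(e$outer_lambdas), 40L)
  expect_gt(length(unique(e$outer_lambdas)), 1L)
  # held-out ROC is internally consistent with the outer AUC
  expect_lt(abs(psapredict:::trapezoid_area(e$roc_points$fpr,
                                            e$roc_points$tpr) -
                  e$auc_outer), 1e-12)
})

test_that("reselection inside the outer loop is supported", {
  cfg <- cohort_config(n_per_arm = 15, true_intercept = 0.9,
                       true_beta = c(haq = -2.5),
                       true_treatment_effects = c(MTX_DN = 0, TOFA_DN = 0,
                                                  ETN_DF = 0, TOFA_DF = 0))
  co <- simulate_cohort(cfg, seed = 39)
  e <- suppressWarnings(
    nested_loocv(co, "homogeneous", candidates = c("haq", "bmi", "sex"),
                 reselect = TRUE, nfolds_inner = 10))
  expect_equal(nrow(e$held_out), 60L)
  expect_true(is.finite(e$auc_outer))
})
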