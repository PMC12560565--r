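sim_logit_data <- function(n, p, seed, beta = NULL, intercept = 0.2) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    if (is.null(beta)) beta <- rep(0, p)
    y <- rbinom(n, 1, plogis(intercept + drop(x %*% beta)))
    list(x = x, y = y)
  })
}

test_that("a very large penalty gives the null model exactly", {
  d <- sim_logit_data(80, 5, 1, beta = c(1, -1, 0.5, 0, 0))
  fit <- fit_penalized(d$x, d$y, alpha = 0.5, lambda = 1e6)
  expect_identical(unname(fit$coefficients), rep(0, 5))
  expect_equal(fit$intercept, qlogis(mean(d$y)), tolerance = 1e-6)
})

test_that("near-zero Ridge penalty matches the unpenalized ML fit", {
  d <- sim_logit_data(500, 4, 2, beta = c(1, -0.5, 0.3, 0))
  fit <- fit_penalized(d$x, d$y, alpha = 0, lambda = 1e-8)
  ml <- glm(d$y ~ d$x, family = binomial())
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) - coef(ml))), 1e-3)
})

test_that("the returned solution is a local (hence global) minimum", {
  d <- sim_logit_data(30, 3, 3, beta = c(0.8, 0, -0.8))
  for (alpha in c(0, 0.5)) {
    fit <- fit_penalized(d$x, d$y, alpha = alpha, lambda = 0.05)
    f0 <- pen_objective(d$x, d$y, fit$intercept, fit$coefficients,
                        alpha, 0.05)
    expect_equal(f0, fit$objective, tolerance = 1e-9)
    perturbed <- withr::with_seed(4, replicate(100, {
      delta <- rnorm(4, 0, 0.01)
      pen_objective(d$x, d$y, fit$intercept + delta[1],
                    fit$coefficients + delta[-1], alpha, 0.05)
    }))
    expect_true(all(perturbed >= f0 - 1e-12))
  }
})

test_that("fits agree with an independent penalized solver", {
  # glmnet, with its internal standardization off, solves the identical
  # objective and serves as the independent cross-check
  library(glmnet)
  d <- sim_logit_data(300, 6, 5, beta = c(1, -0.6, 0.4, 0, 0, 0))
  for (alpha in c(0, 0.5, 1)) {
    gn <- glmnet(d$x, d$y, family = "binomial", alpha = alpha,
                 lambda = 0.04, standardize = FALSE, thresh = 1e-14)
    fit <- fit_penalized(d$x, d$y, alpha = alpha, lambda = 0.04)
    expect_lt(max(abs(c(fit$intercept, fit$coefficients) -
                        as.numeric(coef(gn)))), 1e-6)
  }
  # penalty factors exempting columns (glmnet rescales factors to sum p)
  pf <- c(0, 1, 1, 0, 1, 1)
  gn <- glmnet(d$x, d$y, family = "binomial", alpha = 0.5, lambda = 0.03,
               standardize = FALSE, thresh = 1e-14, penalty.factor = pf)
  fit <- fit_penalized(d$x, d$y, alpha = 0.5,
                       lambda = 0.03 * length(pf) / sum(pf),
                       penalty_factor = pf)
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) -
                      as.numeric(coef(gn)))), 1e-6)
})

test_that("Ridge coefficient norm shrinks monotonically in lambda", {
  d <- sim_logit_data(120, 5, 6, beta = c(1, -1, 0.5, 0.2, 0))
  lams <- exp(seq(log(10), log(1e-4), length.out = 40))
  fit <- psapredict:::cd_logistic_path(d$x, as.numeric(d$y), 0, lams,
                                       rep(1, 5))
  norms <- sqrt(colSums(fit$beta^2))
  expect_true(all(diff(norms) >= -1e-10)) # lambda decreasing, norm growing
})

test_that("elastic-net support size is non-increasing in lambda", {
  d <- sim_logit_data(150, 8, 7, beta = c(1.2, -0.8, 0.5, 0.3, 0, 0, 0, 0))
  cvp <- cv_path(d$x, d$y, alpha = 0.5, nfolds = 10)
  nz <- cvp$path$n_nonzero
  # checked empirically; exact monotonicity can fail, so only log violations
  violations <- sum(diff(nz) < 0)
  if (violations > 0) {
    message(sprintf("support-size monotonicity violations on path: %d",
                    violations))
  }
  expect_lt(violations, length(nz) / 4)
  # the path starts at the null model at lambda_max
  expect_equal(nz[1], 0)
})

test_that("fit is invariant to row permutation", {
  d <- sim_logit_data(90, 4, 8, beta = c(0.7, -0.7, 0, 0))
  perm <- withr::with_seed(9, sample(90))
  f1 <- fit_penalized(d$x, d$y, alpha = 0.5, lambda = 0.02)
  f2 <- fit_penalized(d$x[perm, ], d$y[perm], alpha = 0.5, lambda = 0.02)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-9)
})

test_that("LOOCV deviance equals the brute-force leave-one-out loop", {
  d <- sim_logit_data(12, 2, 10, beta = c(1, -1))
  for (alpha in c(0, 0.5)) {
    lams <- lambda_grid(d$x, d$y, alpha = alpha, nlambda = 30)
    # a strong signal at n = 12 legitimately prefers the smallest penalty,
    # which triggers the extend-the-grid warning
    cvp <- suppressWarnings(cv_path(d$x, d$y, alpha = alpha, lambda = lams))
    bf <- bf_loocv_deviance(d$x, d$y, alpha, lams)
    expect_lt(max(abs(cvp$path$deviance - bf)), 1e-10)
    expect_gte(cvp$lambda_1se, cvp$lambda_min)
    expect_true(all(c(cvp$lambda_1se, cvp$lambda_min) %in% cvp$path$lambda))
  }
})

test_that("CV deviance is invariant to fold relabelling and order", {
  d <- sim_logit_data(40, 3, 11, beta = c(1, 0, -1))
  foldid <- rep_len(1:5, 40)
  relabel <- c(3, 5, 1, 4, 2)[foldid]
  c1 <- cv_path(d$x, d$y, alpha = 0.5, foldid = foldid)
  c2 <- cv_path(d$x, d$y, alpha = 0.5, foldid = relabel,
                lambda = c1$path$lambda)
  expect_equal(c1$path$deviance, c2$path$deviance, tolerance = 1e-12)
})

test_that("pure-noise outcomes select the strongest regularisation", {
  at_top <- vapply(1:20, function(s) {
    d <- sim_logit_data(40, 4, 300 + s, beta = rep(0, 4), intercept = 0)
    cvp <- cv_path(d$x, d$y, alpha = 0, nfolds = 10)
    # lambda_1se in the top (most regularised) decile of the grid
    which(cvp$path$lambda == cvp$lambda_1se) <= 10
  }, logical(1))
  expect_gt(mean(at_top), 0.5)
})

test_that("degenerate inputs are rejected or flagged", {
  d <- sim_logit_data(30, 3, 12)
  expect_error(fit_penalized(d$x, rep(1, 30), alpha = 0, lambda = 1),
               "classes")
  expect_error(fit_penalized(d$x, d$y, alpha = 0, lambda = 0), "lambda")
  expect_error(fit_penalized(d$x, d$y, alpha = 2, lambda = 1), "alpha")
  expect_error(cv_path(d$x, d$y, lambda = c(1, 2, 3)), "decreasing")
  # a training fold containing every responder leaves a one-class fold
  y <- c(rep(0, 28), 1, 1)
  foldid <- c(rep_len(2:6, 28), 1, 1)
  expect_warning(cv_path(d$x, y, alpha = 0, foldid = foldid), "one-class")
})
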