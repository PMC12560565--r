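# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# MDA checklist re-count: explicit per-criterion if/else walk
mda_oracle_count <- function(tjc68, sjc66, bsa, vas_pain, vas_patient_global,
                             haq, lei) {
  met <- 0L
  if (tjc68 <= 1) met <- met + 1L
  if (sjc66 <= 1) met <- met + 1L
  if (bsa <= 3) met <- met + 1L
  if (vas_pain <= 15) met <- met + 1L
  if (vas_patient_global <= 20) met <- met + 1L
  if (haq <= 0.5) met <- met + 1L
  if (lei <= 1) met <- met + 1L
  met
}

# O(n^2) pairwise concordance count with 0.5 for ties
auc_oracle <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# brute-force leave-one-out CV deviance: refits the whole path from scratch
# on every n-1 subset and scores the held-out patient
bf_loocv_deviance <- function(x, y, alpha, lambda, penalty = rep(1, ncol(x))) {
  n <- length(y)
  dev <- matrix(NA_real_, n, length(lambda))
  for (i in seq_len(n)) {
    fit <- psapredict:::cd_logistic_path(x[-i, , drop = FALSE],
                                         as.numeric(y[-i]), alpha, lambda,
                                         as.numeric(penalty))
    eta <- fit$a0 + drop(x[i, ] %*% fit$beta)
    dev[i, ] <- 2 * (log1p(exp(-abs(eta))) + pmax(eta, 0) - y[i] * eta)
  }
  colMeans(dev)
}

# penalized logistic objective recomputed in R
pen_objective <- function(x, y, intercept, beta, alpha, lambda,
                          penalty = rep(1, ncol(x))) {
  eta <- drop(intercept + x %*% beta)
  nll <- mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
  nll + lambda * sum(penalty * (alpha * abs(beta) + (1 - alpha) / 2 * beta^2))
}

# minimal four-arm cohort with independent noise covariates
noise_cohort <- function(n, p = 3, seed = 1, prob = 0.5) {
  withr::with_seed(seed, {
    arm <- rep(c("MTX_DN", "TOFA_DN", "ETN_DF", "TOFA_DF"), length.out = n)
    covs <- stats::setNames(
      lapply(seq_len(p), function(j) rnorm(n)), paste0("x", seq_len(p)))
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      arm = arm,
      stratum = ifelse(arm %in% c("MTX_DN", "TOFA_DN"), "DN", "DF"),
      !!!covs,
      mda_week16 = rbinom(n, 1, prob))
  })
}

true_predictors <- c("haq", "lei", "tjc68", "vas_physician_global",
                     "tnfi_history")
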