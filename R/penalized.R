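#' Fit a penalized logistic regression at one penalty value
#'
#' Minimizes the objective
#' \deqn{\frac{1}{n}\sum_i \left[\log(1+e^{\eta_i}) - y_i\eta_i\right] +
#'   \lambda \sum_j \gamma_j\left(\alpha|\beta_j| +
#'   \frac{1-\alpha}{2}\beta_j^2\right)}
#' with \eqn{\eta = \beta_0 + X\beta}, by iteratively reweighted least
#' squares with coordinate descent. The intercept is never penalized;
#' per-column penalty factors \eqn{\gamma_j} allow exempting forced columns
#' (e.g. main effects during interaction selection). `alpha = 0` is Ridge,
#' `alpha = 1` the lasso.
#'
#' @param x Numeric predictor matrix (no intercept column).
#' @param y Binary 0/1 outcome vector.
#' @param alpha Elastic-net mixing parameter in \[0, 1\].
#' @param lambda Penalty strength (single positive value).
#' @param penalty_factor Per-column penalty factor; 0 exempts a column.
#' @param tol Relative tolerance on the objective between IRLS steps.
#' @param maxit Maximum IRLS iterations.
#' @return A `penfit` object: `intercept`, named `coefficients`, `alpha`,
#'   `lambda`, `objective`, `converged`, `n_iter`, `nobs`.
#' @export
fit_penalized <- function(x, y, alpha = 0, lambda,
                          penalty_factor = rep(1, ncol(x)),
                          tol = 1e-7, maxit = 1e5) {
  check_xy(x, y, alpha, lambda)
  fit <- cd_logistic_path(x, as.numeric(y), alpha, lambda,
                          as.numeric(penalty_factor), tol, as.integer(maxit))
  if (!all(fit$converged)) {
    warn(sprintf("Penalized fit did not converge in %d iterations.",
                 as.integer(maxit)))
  }
  new_penfit(fit$a0[1], stats::setNames(fit$beta[, 1], colnames(x)),
             alpha, lambda, penalty_factor, fit$objective[1],
             all(fit$converged), fit$niter[1], length(y))
}

new_penfit <- function(intercept, coefficients, alpha, lambda,
                       penalty_factor, objective, converged, n_iter, nobs) {
  structure(list(intercept = intercept, coefficients = coefficients,
                 alpha = alpha, lambda = lambda,
                 penalty_factor = penalty_factor, objective = objective,
                 converged = converged, n_iter = n_iter, nobs = nobs),
            class = "penfit")
}

check_xy <- function(x, y, alpha, lambda = 1) {
  if (!is.matrix(x)) abort("x must be a numeric matrix.")
  if (length(y) != nrow(x)) abort("length(y) must equal nrow(x).")
  if (!all(y %in% c(0, 1))) abort("y must be binary 0/1.")
  if (length(unique(y)) < 2L) abort("y must contain both outcome classes.")
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1].")
  if (any(lambda < 0)) abort("lambda must be non-negative.")
  if (any(lambda == 0)) {
    abort("lambda = 0 is not supported; use a small positive lambda.")
  }
  invisible(TRUE)
}

#' @exportS3Method
predict.penfit <- function(object, newx, type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- drop(object$intercept + newx %*% object$coefficients)
  if (type == "response") inv_logit(eta) else eta
}

#' @exportS3Method
print.penfit <- function(x, ...) {
  cat(sprintf("Penalized logistic fit (alpha = %g, lambda = %.4g)\n",
              x$alpha, x$lambda))
  cat(sprintf("  %d coefficients, %d nonzero; converged: %s\n",
              length(x$coefficients), sum(x$coefficients != 0), x$converged))
  invisible(x)
}

#' @exportS3Method
tidy.penfit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients)),
    penalized = c(FALSE, x$penalty_factor > 0))
}

#' @exportS3Method
glance.penfit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, lambda = x$lambda,
                 n_nonzero = sum(x$coefficients != 0),
                 objective = x$objective, converged = x$converged,
                 n_iter = x$n_iter, nobs = x$nobs)
}

#' Pathwise penalty grid
#'
#' Standard pathwise grid: `nlambda` log-spaced values from the smallest
#' penalty that zeroes every penalized coefficient (lambda_max, computed
#' from the score of the model with only unpenalized columns) down to
#' `lambda_min_ratio * lambda_max`. For Ridge (`alpha = 0`) lambda_max is
#' taken at an effective mixing of 0.001, the usual convention since the
#' Ridge path never reaches the null model exactly.
#'
#' @inheritParams fit_penalized
#' @param nlambda Number of grid points.
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty.
#' @return Decreasing vector of penalties.
#' @export
lambda_grid <- function(x, y, alpha = 0, penalty_factor = rep(1, ncol(x)),
                        nlambda = 100, lambda_min_ratio = NULL) {
  # the Ridge cap sits 1000x above the elastic-net entry point, so the grid
  # descends further to span the same effective range of shrinkage
  if (is.null(lambda_min_ratio)) {
    lambda_min_ratio <- if (alpha < 1e-3) 1e-7 else 1e-4
  }
  check_xy(x, y, alpha)
  y <- as.numeric(y)
  if (all(penalty_factor > 0)) {
    p0 <- rep(mean(y), length(y))
  } else {
    base <- cd_logistic_path(x, y, alpha, 1e9, as.numeric(penalty_factor))
    eta <- drop(base$a0[1] + x %*% base$beta[, 1])
    p0 <- inv_logit(eta)
  }
  g <- abs(drop(crossprod(x, y - p0))) / length(y)
  pen <- penalty_factor > 0
  lam_max <- max(g[pen] / penalty_factor[pen]) / max(alpha, 1e-3)
  if (!is.finite(lam_max) || lam_max <= 0) lam_max <- 1
  # sit strictly above the entry point so the path truly starts at the null
  # model instead of numerically on the soft-threshold boundary
  lam_max <- lam_max * 1.000001
  exp(seq(log(lam_max), log(lam_max * lambda_min_ratio), length.out = nlambda))
}

#' Cross-validated penalty path for penalized logistic regression
#'
#' Fits the full regularization path and estimates, for every penalty on the
#' grid, the cross-validated binomial deviance: each fold's model is refit
#' from scratch on the remaining rows and the held-out observations'
#' deviances are averaged. With `nfolds = NULL` (the default) this is
#' leave-one-out cross-validation, as used at the trial's sample size; for
#' large simulated cohorts a smaller `nfolds` gives K-fold CV with
#' deterministic class-balanced fold assignment. The standard error is
#' computed across the per-observation held-out deviances.
#'
#' `lambda_min` minimizes the mean CV deviance; `lambda_1se` is the largest
#' penalty whose mean CV deviance is within one standard error of that
#' minimum (the more regularised choice used throughout the pipeline).
#'
#' @inheritParams fit_penalized
#' @inheritParams lambda_grid
#' @param nfolds Number of CV folds; `NULL` for leave-one-out.
#' @param foldid Optional explicit 1-based fold assignment.
#' @param lambda Optional explicit decreasing penalty grid.
#' @return A `cv_path` object: tibble `path` (lambda, deviance, se,
#'   n_nonzero), `lambda_min`, `lambda_1se`, and the full-data path fit.
#' @export
cv_path <- function(x, y, alpha = 0, penalty_factor = rep(1, ncol(x)),
                    nfolds = NULL, foldid = NULL, lambda = NULL,
                    nlambda = 100, lambda_min_ratio = NULL,
                    tol = 1e-7, maxit = 1e5) {
  check_xy(x, y, alpha)
  n <- length(y)
  y <- as.numeric(y)
  if (is.null(lambda)) {
    lambda <- lambda_grid(x, y, alpha, penalty_factor, nlambda,
                          lambda_min_ratio)
  }
  if (is.unsorted(rev(lambda), strictly = TRUE)) {
    abort("lambda grid must be strictly decreasing.")
  }
  if (is.null(foldid)) {
    if (is.null(nfolds)) {
      foldid <- seq_len(n)
    } else {
      # deterministic class-balanced assignment: cycle folds within outcome
      foldid <- integer(n)
      foldid[order(y)] <- rep_len(seq_len(nfolds), n)
    }
  }
  if (is.null(nfolds)) nfolds <- max(foldid)
  if (n < 10) abort("Cross-validation requires at least 10 observations.")

  dev <- cd_logistic_cv(x, y, alpha, lambda, as.numeric(penalty_factor),
                        as.integer(foldid), tol, as.integer(maxit))
  skipped <- which(is.na(dev[, 1]))
  if (length(skipped)) {
    warn(sprintf(
      "%d observation(s) in one-class training folds skipped in CV.",
      length(skipped)))
  }
  m <- apply(dev, 2, mean, na.rm = TRUE)
  se <- apply(dev, 2, function(d) {
    d <- d[!is.na(d)]
    stats::sd(d) / sqrt(length(d))
  })
  i_min <- which.min(m)
  if (i_min == length(lambda)) {
    warn("CV deviance is minimized at the smallest penalty; extend the grid.")
  }
  within <- which(m <= m[i_min] + se[i_min])
  i_1se <- min(within) # grid is decreasing, so the first index is largest
  full <- cd_logistic_path(x, y, alpha, lambda, as.numeric(penalty_factor),
                           tol, as.integer(maxit))
  structure(
    list(path = tibble::tibble(lambda = lambda, deviance = m, se = se,
                               n_nonzero = colSums(full$beta != 0)),
         lambda_min = lambda[i_min], lambda_1se = lambda[i_1se],
         alpha = alpha, penalty_factor = penalty_factor,
         colnames = colnames(x), fit = full, nobs = n,
         n_skipped = length(skipped)),
    class = "cv_path")
}

#' @rdname cv_path
#' @export
loocv_path <- function(x, y, alpha = 0, penalty_factor = rep(1, ncol(x)),
                       ...) {
  cv_path(x, y, alpha, penalty_factor, nfolds = NULL, ...)
}

#' Extract the path solution at a chosen penalty
#'
#' @param cvp A `cv_path` object.
#' @param s The penalty to extract: `"lambda_1se"` (default),
#'   `"lambda_min"`, or a numeric value on the grid.
#' @return A `penfit` object at that penalty, taken from the warm-started
#'   full-data path (so it is exactly the fit whose nonzero pattern CV
#'   selection reports).
#' @export
fit_at <- function(cvp, s = "lambda_1se") {
  lam <- if (is.character(s)) cvp[[s]] else s
  i <- which(abs(cvp$path$lambda - lam) < 1e-12 * max(1, lam))
  if (!length(i)) abort("Requested lambda is not on the CV grid.")
  i <- i[1]
  new_penfit(cvp$fit$a0[i],
             stats::setNames(cvp$fit$beta[, i], cvp$colnames),
             cvp$alpha, cvp$path$lambda[i], cvp$penalty_factor,
             cvp$fit$objective[i], cvp$fit$converged[i], cvp$fit$niter[i],
             cvp$nobs)
}

#' @exportS3Method
print.cv_path <- function(x, ...) {
  cat(sprintf(
    "Cross-validated penalty path (alpha = %g, %d lambdas, n = %d)\n",
    x$alpha, nrow(x$path), x$nobs))
  cat(sprintf("  lambda_min = %.4g, lambda_1se = %.4g\n",
              x$lambda_min, x$lambda_1se))
  invisible(x)
}

#' @exportS3Method
tidy.cv_path <- function(x, ...) x$path

#' Plot a cross-validated penalty path
#'
#' Mean cross-validated binomial deviance (with one-standard-error ribbon)
#' against log lambda, with the `lambda_min` and `lambda_1se` choices marked.
#'
#' @param object A `cv_path` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.cv_path <- function(object, ...) {
  df <- object$path
  ggplot2::ggplot(df, ggplot2::aes(x = log(.data$lambda),
                                   y = .data$deviance)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$deviance - .data$se,
                                      ymax = .data$deviance + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$lambda_min),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = log(object$lambda_1se),
                        linetype = "dotted") +
    ggplot2::labs(x = expression(log(lambda)),
                  y = "Mean CV binomial deviance",
                  title = sprintf("alpha = %g (dashed: lambda_min, dotted: lambda_1se)",
                                  object$alpha))
}
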