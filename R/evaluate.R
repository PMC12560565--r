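#' Area under the ROC curve by the Mann-Whitney statistic
#'
#' The probability that a randomly chosen responder receives a higher
#' predicted probability than a randomly chosen non-responder, with ties
#' counted as 1/2 (midrank convention).
#'
#' @param probabilities Predicted probabilities (any monotone score works).
#' @param outcomes Binary 0/1 outcomes.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.9, 0.1), c(1, 0))
auc <- function(probabilities, outcomes) {
  if (length(probabilities) != length(outcomes)) {
    abort("probabilities and outcomes must have equal length.")
  }
  if (!all(outcomes %in% c(0, 1)) || length(unique(outcomes)) < 2L) {
    abort("outcomes must be binary 0/1 with both classes present.")
  }
  r <- rank(probabilities) # midranks handle ties as 1/2
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' One (FPR, TPR) point per distinct threshold, from (0, 0) to (1, 1),
#' monotone non-decreasing in both coordinates. The trapezoidal area under
#' the returned points equals [auc()] exactly (ties contribute the diagonal
#' segment whose trapezoid is the midrank 1/2 correction).
#'
#' @inheritParams auc
#' @return Tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(probabilities, outcomes) {
  if (!all(outcomes %in% c(0, 1)) || length(unique(outcomes)) < 2L) {
    abort("outcomes must be binary 0/1 with both classes present.")
  }
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]
  y <- outcomes[ord]
  last <- !duplicated(p, fromLast = TRUE) # last index of each threshold run
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  tibble::tibble(
    threshold = c(Inf, p[last]),
    fpr = c(0, cumsum(y == 0)[last] / n0),
    tpr = c(0, cumsum(y == 1)[last] / n1))
}

trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Plot ROC curves
#'
#' @param roc A tibble from [roc_curve()], or a named list of them (one
#'   curve per model).
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  if (!is.data.frame(roc)) {
    roc <- dplyr::bind_rows(roc, .id = "model")
  } else {
    roc$model <- "model"
  }
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL)
}

fit_strategy <- function(strategy, data, selected, outcome, transforms,
                         nfolds, fixed_lambda = NULL, ...) {
  switch(strategy,
    homogeneous = fit_homogeneous(data, selected, outcome = outcome,
                                  transforms = transforms, nfolds = nfolds,
                                  lambda = fixed_lambda, ...),
    risk = fit_risk_model(data, selected, outcome = outcome,
                          transforms = transforms, nfolds = nfolds,
                          lambda_stage1 = fixed_lambda,
                          lambda_stage2 = fixed_lambda, ...),
    effect = fit_effect_model(data, selected, outcome = outcome,
                              transforms = transforms, nfolds = nfolds,
                              lambda = fixed_lambda, ...),
    abort(sprintf("Unknown strategy '%s'.", strategy)))
}

model_lambda <- function(model) {
  if (inherits(model, "risk_model")) model$stage2$lambda else model$fit$lambda
}

#' Nested leave-one-out cross-validated performance of a strategy
#'
#' Outer loop: each patient is left out in turn and the entire fitting
#' recipe is rerun on the remaining patients — including, for the risk
#' model, stage-1 refitting and linear-predictor recomputation, and
#' optionally predictor reselection — with the penalty tuned by an inner
#' leave-one-out loop (`lambda_1se`). The left-out patient's response
#' probability is predicted under their own arm, and the AUC-ROC over the
#' held-out pairs estimates out-of-sample performance. The resubstitution
#' AUC of the model tuned on the full data (`auc_inner`) is reported
#' alongside; it is systematically optimistic relative to `auc_outer`.
#'
#' By default predictor selection is performed once on the full data and
#' the outer loop only re-tunes and refits the models (the two-phase
#' presentation of the pipeline); `reselect = TRUE` repeats the elastic-net
#' selection inside every outer fold for a fully honest estimate.
#'
#' @param cohort Cohort data frame.
#' @param strategy `"homogeneous"`, `"risk"` or `"effect"`.
#' @param selected_predictors Predictors for the models (required unless
#'   `reselect = TRUE`).
#' @param candidates Candidate predictors for reselection.
#' @param reselect Repeat predictor selection in every outer fold?
#' @param outcome Binary outcome column.
#' @param transforms Optional [screen_transforms()] result.
#' @param nfolds_inner Folds for the inner tuning loop (`NULL` =
#'   leave-one-out).
#' @param fixed_lambda Optional fixed penalty; skips the inner loop, so the
#'   procedure reduces to plain leave-one-out cross-validation.
#' @param ... Passed to the strategy fitting function.
#' @return A `nested_cv` object: per-patient held-out probabilities,
#'   per-fold tuned lambdas, `auc_outer`, `auc_inner`, `final_lambda`
#'   (tuned on the full data), ROC points, and the full-data model.
#' @export
nested_loocv <- function(cohort, strategy = c("homogeneous", "risk", "effect"),
                         selected_predictors = NULL, candidates = NULL,
                         reselect = FALSE, outcome = "mda_week16",
                         transforms = NULL, nfolds_inner = NULL,
                         fixed_lambda = NULL, ...) {
  strategy <- match.arg(strategy)
  n <- nrow(cohort)
  if (n < 20) abort("Nested cross-validation requires at least 20 patients.")
  y <- cohort[[outcome]]
  if (length(unique(y)) < 2L) abort("Outcome must contain both classes.")
  if (reselect && is.null(candidates)) {
    abort("candidates must be given when reselect = TRUE.")
  }
  if (!reselect && is.null(selected_predictors)) {
    abort("selected_predictors must be given when reselect = FALSE.")
  }

  held_out <- rep(NA_real_, n)
  outer_lambdas <- rep(NA_real_, n)
  skipped <- integer()
  for (i in seq_len(n)) {
    train <- cohort[-i, , drop = FALSE]
    if (length(unique(train[[outcome]])) < 2L) {
      skipped <- c(skipped, i)
      next
    }
    sel <- selected_predictors
    if (reselect) {
      sel <- tryCatch(
        select_union(train, candidates, outcome = outcome,
                     transforms = transforms, nfolds = nfolds_inner)$union,
        error = function(e) NULL)
      if (is.null(sel)) {
        skipped <- c(skipped, i)
        next
      }
    }
    model <- fit_strategy(strategy, train, sel, outcome, transforms,
                          nfolds_inner, fixed_lambda, ...)
    held_out[i] <- predict_response(model, cohort[i, , drop = FALSE])
    outer_lambdas[i] <- model_lambda(model)
  }
  if (length(skipped)) {
    warn(sprintf("%d outer fold(s) skipped (degenerate training data).",
                 length(skipped)))
  }
  ok <- !is.na(held_out)
  auc_outer <- auc(held_out[ok], y[ok])
  roc <- roc_curve(held_out[ok], y[ok])

  final_sel <- if (reselect) {
    select_union(cohort, candidates, outcome = outcome,
                 transforms = transforms, nfolds = nfolds_inner)$union
  } else {
    selected_predictors
  }
  final_model <- fit_strategy(strategy, cohort, final_sel, outcome,
                              transforms, nfolds_inner, fixed_lambda, ...)
  p_full <- predict_response(final_model, cohort)
  structure(
    list(strategy = strategy,
         held_out = tibble::tibble(
           patient_id = cohort$patient_id %||% as.character(seq_len(n)),
           outcome = y, probability = held_out),
         outer_lambdas = outer_lambdas,
         auc_outer = auc_outer, auc_inner = auc(p_full, y),
         roc_points = roc, final_lambda = model_lambda(final_model),
         final_model = final_model, n = n, skipped = skipped),
    class = "nested_cv")
}

#' @exportS3Method
print.nested_cv <- function(x, ...) {
  cat(sprintf("Nested LOOCV, %s strategy (n = %d)\n", x$strategy, x$n))
  cat(sprintf("  outer AUC-ROC = %.3f (resubstitution of tuned model: %.3f)\n",
              x$auc_outer, x$auc_inner))
  cat(sprintf("  final lambda = %.4g\n", x$final_lambda))
  invisible(x)
}

#' @exportS3Method
glance.nested_cv <- function(x, ...) {
  tibble::tibble(strategy = x$strategy, n = x$n,
                 auc_outer = x$auc_outer, auc_inner = x$auc_inner,
                 final_lambda = x$final_lambda,
                 n_skipped_folds = length(x$skipped))
}

#' @exportS3Method
tidy.nested_cv <- function(x, ...) x$held_out

#' @exportS3Method
autoplot.nested_cv <- function(object, ...) {
  plot_roc(object$roc_points) +
    ggplot2::labs(title = sprintf("%s strategy: outer AUC-ROC = %.2f",
                                  object$strategy, object$auc_outer))
}
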