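#' Fit the homogeneous treatment-effect model
#'
#' Ridge-penalized logistic regression of the responder outcome on the
#' selected baseline predictors plus the three treatment dummies
#' (reference `MTX_DN`), with the penalty chosen by cross-validated
#' `lambda_1se`. Treatment enters only through main effects, so the model
#' assumes a constant treatment effect on the log-odds scale; the absolute
#' difference in predicted probabilities between treatments still varies
#' across patients with their baseline risk.
#'
#' @param cohort Cohort data frame.
#' @param selected_predictors Character vector of predictor columns.
#' @param outcome Binary outcome column name.
#' @param transforms Optional [screen_transforms()] result.
#' @param nfolds CV folds for the penalty (`NULL` = leave-one-out).
#' @param lambda Optional fixed penalty; skips cross-validation.
#' @param penalize_treatment Are the treatment dummies penalized along with
#'   the predictors (default) or exempted from the penalty?
#' @param ... Passed to [cv_path()].
#' @return A `homogeneous_model` object.
#' @export
fit_homogeneous <- function(cohort, selected_predictors,
                            outcome = "mda_week16", transforms = NULL,
                            nfolds = NULL, lambda = NULL,
                            penalize_treatment = TRUE, ...) {
  if (!length(selected_predictors)) {
    abort("At least one selected predictor is required.")
  }
  dm <- build_design_matrix(cohort, selected_predictors,
                            transforms = transforms,
                            include_treatment = TRUE)
  y <- cohort[[outcome]]
  pf <- rep(1, ncol(dm$x))
  if (!penalize_treatment) pf[grepl("^arm_", colnames(dm$x))] <- 0
  if (is.null(lambda)) {
    cvp <- cv_path(dm$x, y, alpha = 0, penalty_factor = pf,
                   nfolds = nfolds, ...)
    fit <- fit_at(cvp, "lambda_1se")
  } else {
    cvp <- NULL
    fit <- fit_penalized(dm$x, y, alpha = 0, lambda = lambda,
                         penalty_factor = pf)
  }
  structure(list(fit = fit, cv = cvp, design = dm,
                 predictors = selected_predictors, outcome = outcome),
            class = c("homogeneous_model", "psa_model"))
}

# coefficients mapped back from the standardized columns to the analysis
# (transformed but unstandardized) scale
analysis_scale_coefs <- function(fit, design) {
  beta <- fit$coefficients
  a0 <- fit$intercept
  for (v in names(design$center %||% numeric())) {
    if (v %in% names(beta)) {
      a0 <- a0 - beta[[v]] * design$center[[v]] / design$scale[[v]]
      beta[[v]] <- beta[[v]] / design$scale[[v]]
    }
  }
  list(intercept = a0, coefficients = beta)
}

transformed_matrix <- function(spec, data, predictors = spec$predictors) {
  cols <- lapply(predictors, function(v) {
    apply_transform(data[[v]], spec$transform[[v]], spec$offset[[v]])
  })
  x <- do.call(cbind, cols)
  colnames(x) <- predictors
  x
}

#' Fit the risk-modelling treatment-effect strategy
#'
#' Two-stage heterogeneous treatment-effect model. Stage 1 fits a Ridge
#' model of response on the selected predictors among tofacitinib-treated
#' patients of both strata, with a DN/DF stratum indicator as covariate.
#' A linear predictor (LP) is then computed for every patient by
#' multiplying the stage-1 regression coefficients with the patient's
#' predictor values, excluding the intercept and the stratum/treatment
#' terms. Stage 2 is a Ridge model of response on the three treatment
#' dummies, the (standardized) LP, and the three LP-by-treatment
#' interactions, so the predictive effect of all predictors is modified by
#' treatment through the single LP score.
#'
#' @inheritParams fit_homogeneous
#' @param lambda_stage1,lambda_stage2 Optional fixed penalties per stage.
#' @param stage2_penalized Fit stage 2 with Ridge and its own
#'   cross-validated penalty (default) or as unpenalized maximum likelihood.
#' @param penalize_treatment Are the stage-2 treatment dummies penalized?
#' @return A `risk_model` object with `stage1`, `lp_coefficients` (analysis
#'   scale), and `stage2`.
#' @export
fit_risk_model <- function(cohort, selected_predictors,
                           outcome = "mda_week16", transforms = NULL,
                           nfolds = NULL, lambda_stage1 = NULL,
                           lambda_stage2 = NULL, stage2_penalized = TRUE,
                           penalize_treatment = TRUE, ...) {
  if (!length(selected_predictors)) {
    abort("At least one selected predictor is required.")
  }
  tofa <- cohort[cohort$arm %in% c("TOFA_DN", "TOFA_DF"), , drop = FALSE]
  tofa <- dplyr::mutate(tofa, stratum_df = as.numeric(.data$stratum == "DF"))
  preds1 <- selected_predictors[vapply(selected_predictors, function(v) {
    stats::var(as.numeric(tofa[[v]])) > 0
  }, logical(1))]
  if (!length(preds1)) {
    abort("No selected predictor varies among tofacitinib patients.")
  }
  with_stratum <- stats::var(tofa$stratum_df) > 0
  dm1 <- build_design_matrix(tofa, c(preds1, if (with_stratum) "stratum_df"),
                             transforms = transforms,
                             include_treatment = FALSE)
  y1 <- tofa[[outcome]]
  if (is.null(lambda_stage1)) {
    cv1 <- cv_path(dm1$x, y1, alpha = 0, nfolds = nfolds, ...)
    fit1 <- fit_at(cv1, "lambda_1se")
  } else {
    cv1 <- NULL
    fit1 <- fit_penalized(dm1$x, y1, alpha = 0, lambda = lambda_stage1)
  }
  asc <- analysis_scale_coefs(fit1, dm1)
  lp_coef <- asc$coefficients[setdiff(names(asc$coefficients), "stratum_df")]
  if (all(lp_coef == 0)) {
    abort(paste("Stage-1 coefficients are all zero (over-shrunk);",
                "inspect the stage-1 CV path."))
  }

  lp_all <- drop(transformed_matrix(dm1, cohort, names(lp_coef)) %*% lp_coef)
  if (stats::var(lp_all) == 0) {
    abort("Linear predictor has zero variance across the cohort.")
  }
  lp_center <- mean(lp_all)
  lp_scale <- stats::sd(lp_all)

  x2 <- risk_stage2_matrix(cohort$arm, (lp_all - lp_center) / lp_scale)
  y <- cohort[[outcome]]
  pf <- rep(1, ncol(x2))
  if (!penalize_treatment) pf[grepl("^arm_", colnames(x2))] <- 0
  if (!stage2_penalized) {
    g <- stats::glm(y ~ x2, family = binomial())
    fit2 <- new_penfit(unname(coef(g)[1]),
                       stats::setNames(unname(coef(g)[-1]), colnames(x2)),
                       alpha = 0, lambda = 0, penalty_factor = pf * 0,
                       objective = g$deviance / (2 * length(y)),
                       converged = g$converged, n_iter = g$iter,
                       nobs = length(y))
    cv2 <- NULL
  } else if (is.null(lambda_stage2)) {
    cv2 <- cv_path(x2, y, alpha = 0, penalty_factor = pf,
                   nfolds = nfolds, ...)
    fit2 <- fit_at(cv2, "lambda_1se")
  } else {
    cv2 <- NULL
    fit2 <- fit_penalized(x2, y, alpha = 0, lambda = lambda_stage2,
                          penalty_factor = pf)
  }
  structure(list(stage1 = fit1, stage1_cv = cv1, stage1_design = dm1,
                 lp_coefficients = lp_coef, lp_center = lp_center,
                 lp_scale = lp_scale, stage2 = fit2, stage2_cv = cv2,
                 predictors = selected_predictors, outcome = outcome),
            class = c("risk_model", "psa_model"))
}

risk_stage2_matrix <- function(arm, lp_std) {
  d <- arm_dummies(arm)
  inter <- d * lp_std
  colnames(inter) <- paste0("lp:", colnames(d))
  cbind(d, lp = lp_std, inter)
}

#' Compute the risk-model linear predictor for patients
#'
#' The weighted sum of a patient's (transformed) predictor values using the
#' stage-1 tofacitinib-model coefficients, excluding the intercept and
#' stratum/treatment terms. A patient with all predictor values zero has
#' LP exactly 0.
#'
#' @param model A `risk_model`.
#' @param data Patient rows.
#' @param standardized Return the LP on the standardized scale used in
#'   stage 2?
#' @return Numeric vector of linear-predictor values.
#' @export
linear_predictor <- function(model, data, standardized = FALSE) {
  lp <- drop(transformed_matrix(model$stage1_design, data,
                                names(model$lp_coefficients)) %*%
               model$lp_coefficients)
  if (standardized) (lp - model$lp_center) / model$lp_scale else lp
}

#' Fit the effect-modelling treatment-effect strategy
#'
#' Builds all predictor-by-treatment interaction columns (standardized
#' predictor times non-reference arm dummy), selects relevant interactions
#' by elastic net with the main effects and treatment dummies exempt from
#' the penalty, and refits the final model by Ridge on the main effects,
#' treatment, and the selected interactions. With no interaction selected,
#' the final model is exactly the homogeneous treatment-effect model.
#'
#' @inheritParams fit_homogeneous
#' @param alpha_select Elastic-net mixing for interaction selection.
#' @return An `effect_model` object with `selected_interactions`.
#' @export
fit_effect_model <- function(cohort, selected_predictors,
                             outcome = "mda_week16", transforms = NULL,
                             nfolds = NULL, lambda = NULL,
                             alpha_select = 0.5, ...) {
  if (!length(selected_predictors)) {
    abort("At least one selected predictor is required.")
  }
  dm <- build_design_matrix(cohort, selected_predictors,
                            transforms = transforms,
                            include_treatment = TRUE)
  y <- cohort[[outcome]]
  main_cols <- colnames(dm$x)
  inter <- interaction_columns(dm$x, selected_predictors)
  x_sel <- cbind(dm$x, inter)
  pf <- c(rep(0, ncol(dm$x)), rep(1, ncol(inter)))
  cv_sel <- cv_path(x_sel, y, alpha = alpha_select, penalty_factor = pf,
                    nfolds = nfolds, ...)
  fit_sel <- fit_at(cv_sel, "lambda_1se")
  sel_cols <- colnames(inter)[fit_sel$coefficients[colnames(inter)] != 0]

  x_final <- cbind(dm$x, inter[, sel_cols, drop = FALSE])
  if (is.null(lambda)) {
    cvf <- cv_path(x_final, y, alpha = 0, nfolds = nfolds, ...)
    fit <- fit_at(cvf, "lambda_1se")
  } else {
    cvf <- NULL
    fit <- fit_penalized(x_final, y, alpha = 0, lambda = lambda)
  }
  selected_interactions <- tibble::tibble(
    predictor = sub(":arm_.*$", "", sel_cols),
    arm = sub("^.*:arm_", "", sel_cols))
  structure(list(fit = fit, cv = cvf, selection_cv = cv_sel,
                 design = dm, selected_interactions = selected_interactions,
                 predictors = selected_predictors, outcome = outcome),
            class = c("effect_model", "psa_model"))
}

# products of each (standardized) predictor column with the three
# non-reference arm dummies; reference-arm interactions are never built
interaction_columns <- function(x, predictors) {
  dcols <- grep("^arm_", colnames(x), value = TRUE)
  out <- do.call(cbind, lapply(predictors, function(v) {
    m <- x[, v] * x[, dcols, drop = FALSE]
    colnames(m) <- paste0(v, ":", dcols)
    m
  }))
  out
}

#' Predicted response probability under a given (or observed) treatment arm
#'
#' @param model A fitted `homogeneous_model`, `risk_model` or
#'   `effect_model`.
#' @param data Patient rows with all predictor columns (and `arm`,
#'   `stratum`).
#' @param arm Optional arm override (length 1 or `nrow(data)`). The arm must
#'   belong to each patient's own stratum; cross-stratum counterfactuals are
#'   refused.
#' @return Vector of predicted response probabilities.
#' @export
predict_response <- function(model, data, arm = NULL) {
  if (!is.null(arm)) {
    if (length(arm) == 1L) arm <- rep(arm, nrow(data))
    bad <- stratum_of_arm(arm) != data$stratum
    if (any(bad)) {
      abort(sprintf(
        "Cross-stratum counterfactual refused for patient %s (%s under %s).",
        (data$patient_id %||% which(bad))[bad][1],
        data$stratum[bad][1], arm[bad][1]))
    }
  }
  UseMethod("predict_response")
}

#' @exportS3Method psapredict::predict_response
predict_response.homogeneous_model <- function(model, data, arm = NULL) {
  x <- project_design(model$design, data, arm = arm)
  predict(model$fit, x, type = "response")
}

#' @exportS3Method psapredict::predict_response
predict_response.risk_model <- function(model, data, arm = NULL) {
  lp_std <- linear_predictor(model, data, standardized = TRUE)
  a <- arm %||% data$arm
  if (length(a) == 1L) a <- rep(a, nrow(data))
  x2 <- risk_stage2_matrix(a, lp_std)
  predict(model$stage2, x2, type = "response")
}

#' @exportS3Method psapredict::predict_response
predict_response.effect_model <- function(model, data, arm = NULL) {
  x <- project_design(model$design, data, arm = arm)
  inter <- interaction_columns(x, model$predictors)
  keep <- names(model$fit$coefficients)
  x_final <- cbind(x, inter)[, keep, drop = FALSE]
  predict(model$fit, x_final, type = "response")
}

#' @exportS3Method
tidy.psa_model <- function(x, ...) tidy(x$fit)

#' @exportS3Method
glance.psa_model <- function(x, ...) {
  g <- glance(x$fit)
  g$strategy <- class(x)[1]
  g
}

#' Per-patient counterfactual response probabilities
#'
#' For every patient, evaluates the fitted model twice with the baseline
#' covariates held fixed: once under the stratum-consistent tofacitinib arm
#' and once under the stratum comparator (methotrexate for DN, add-on
#' etanercept for DF). Counterfactuals are only formed within a patient's
#' own stratum.
#'
#' @param model A fitted strategy model.
#' @param cohort Patient rows.
#' @return Tibble with `patient_id`, `stratum`, `arm` (observed),
#'   `p_tofacitinib`, `p_comparator`, `delta` (tofacitinib minus
#'   comparator) and `favored` (`"tofacitinib"`, `"methotrexate"`,
#'   `"etanercept"`, or `"tie"`).
#' @export
predict_counterfactuals <- function(model, cohort) {
  tofa_arm <- tofacitinib_arm(cohort$stratum)
  comp_arm <- comparator_arm(cohort$stratum)
  p_t <- predict_response(model, cohort, arm = tofa_arm)
  p_c <- predict_response(model, cohort, arm = comp_arm)
  delta <- p_t - p_c
  tibble::tibble(
    patient_id = cohort$patient_id %||% as.character(seq_len(nrow(cohort))),
    stratum = cohort$stratum, arm = cohort$arm,
    p_tofacitinib = p_t, p_comparator = p_c, delta = delta,
    favored = dplyr::case_when(
      delta > 0 ~ "tofacitinib",
      delta < 0 & cohort$stratum == "DN" ~ "methotrexate",
      delta < 0 ~ "etanercept",
      TRUE ~ "tie"))
}

#' Summarize the clinical impact of counterfactual predictions per stratum
#'
#' Aggregates per-patient counterfactual pairs into the per-stratum impact
#' summary: range and median of the predicted probability difference
#' (tofacitinib minus comparator) and the percentage of patients for whom
#' each treatment has the higher predicted response probability. Exact ties
#' are reported separately and excluded from the percentages.
#'
#' @param pairs Output of [predict_counterfactuals()].
#' @return Tibble with one row per stratum.
#' @export
summarize_impact <- function(pairs) {
  dplyr::summarise(
    dplyr::group_by(pairs, .data$stratum),
    n = dplyr::n(),
    delta_min = min(.data$delta),
    delta_max = max(.data$delta),
    delta_median = stats::median(.data$delta),
    n_ties = sum(.data$favored == "tie"),
    pct_favor_tofacitinib =
      100 * sum(.data$favored == "tofacitinib") / max(1, sum(.data$favored != "tie")),
    pct_favor_comparator =
      100 * sum(!.data$favored %in% c("tofacitinib", "tie")) /
        max(1, sum(.data$favored != "tie")),
    .groups = "drop")
}

#' Plot counterfactual probability pairs
#'
#' Predicted probability of response under the comparator against the
#' tofacitinib-minus-comparator difference, per stratum.
#'
#' @param pairs Output of [predict_counterfactuals()].
#' @return A ggplot object.
#' @export
plot_counterfactuals <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$p_comparator,
                                      y = .data$delta,
                                      colour = .data$stratum)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Predicted P(response) under comparator",
                  y = "P(tofacitinib) - P(comparator)",
                  colour = "Stratum")
}
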