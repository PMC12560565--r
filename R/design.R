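#' Screen log / square-root transformations for skewed predictors
#'
#' For every continuous predictor whose absolute sample skewness exceeds
#' `skewness_threshold`, fits univariable logistic models of the outcome on
#' the identity, natural-log and square-root versions of the predictor and
#' keeps the candidate with the lowest deviance (all candidates spend one
#' degree of freedom, so this is the AIC ordering). Predictors at or below
#' the threshold keep the identity scale without any model being fit.
#'
#' Variables with zeros use `log(x + 1)`; candidates are skipped with a
#' warning for predictors with negative values.
#'
#' @param data Cohort data frame.
#' @param predictors Character vector of continuous predictor columns.
#' @param outcome Name of the binary outcome column.
#' @param skewness_threshold Absolute sample skewness above which the
#'   transformation candidates are evaluated.
#' @return Tibble with one row per predictor: `predictor`, `skewness`,
#'   `screened` (was the gate triggered), per-candidate deviances
#'   (`dev_identity`, `dev_natural_log`, `dev_square_root`) and `chosen`.
#' @export
screen_transforms <- function(data, predictors, outcome = "mda_week16",
                              skewness_threshold = 1) {
  y <- data[[outcome]]
  if (is.null(y)) abort(sprintf("Outcome column '%s' not found.", outcome))
  if (!all(y %in% c(0, 1))) abort("Outcome must be binary 0/1.")
  rows <- lapply(predictors, function(v) {
    x <- data[[v]]
    if (is.null(x)) abort(sprintf("Predictor column '%s' not found.", v))
    sk <- sample_skewness(x)
    out <- tibble::tibble(predictor = v, skewness = sk,
                          screened = abs(sk) > skewness_threshold,
                          dev_identity = NA_real_,
                          dev_natural_log = NA_real_,
                          dev_square_root = NA_real_,
                          chosen = "identity")
    if (!out$screened) return(out)
    # extreme skewed candidates can drive fitted probabilities to 0/1;
    # the deviance comparison is still well defined, so silence glm here
    uni_dev <- function(z) suppressWarnings(stats::glm(y ~ z, family = binomial())$deviance)
    devs <- c(identity = uni_dev(x))
    if (any(x < 0)) {
      warn(sprintf(
        "Predictor '%s' has negative values; log/sqrt candidates skipped.", v))
    } else {
      xl <- if (any(x == 0)) log1p(x) else log(x)
      devs["natural_log"] <- uni_dev(xl)
      devs["square_root"] <- uni_dev(sqrt(x))
    }
    out$dev_identity <- devs[["identity"]]
    out$dev_natural_log <- devs["natural_log"][[1]] %||% NA_real_
    out$dev_square_root <- devs["square_root"][[1]] %||% NA_real_
    out$chosen <- names(devs)[which.min(devs)]
    out
  })
  dplyr::bind_rows(rows)
}

apply_transform <- function(x, transform, offset = 0) {
  switch(transform,
    identity = x,
    natural_log = log(x + offset),
    square_root = sqrt(x),
    abort(sprintf("Unknown transform '%s'.", transform)))
}

transform_table <- function(predictors, transforms, data) {
  tab <- stats::setNames(rep("identity", length(predictors)), predictors)
  off <- stats::setNames(rep(0, length(predictors)), predictors)
  if (!is.null(transforms)) {
    for (i in seq_len(nrow(transforms))) {
      v <- transforms$predictor[i]
      if (v %in% predictors) {
        tab[v] <- transforms$chosen[i]
        if (tab[v] == "natural_log" && any(data[[v]] == 0)) off[v] <- 1
      }
    }
  }
  list(transform = tab, offset = off)
}

#' Build the numeric predictor matrix for penalized fitting
#'
#' Applies the chosen transformations, encodes binary predictors as 0/1 and
#' the four-arm treatment as three dummies against the `MTX_DN` reference,
#' and standardizes continuous columns to mean 0, SD 1 on the training rows.
#' Treatment dummies and binary predictors are left unstandardized so the
#' reference-category parameterisation stays interpretable. The
#' standardization parameters are stored so new patients can be projected
#' onto the identical scale with [project_design()].
#'
#' @param data Cohort data frame (training rows).
#' @param predictors Character vector of predictor columns to include.
#' @param transforms Optional result of [screen_transforms()].
#' @param include_treatment Add the three treatment dummies?
#' @param standardize Standardize continuous columns?
#' @return A `design_spec` object with elements `x` (the numeric matrix),
#'   `predictors`, `transform`, `center`, `scale`, and encoding metadata.
#' @export
build_design_matrix <- function(data, predictors, transforms = NULL,
                                include_treatment = TRUE, standardize = TRUE) {
  missing_cols <- setdiff(predictors, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Predictor column '%s' not found in data.", missing_cols[1]))
  }
  tt <- transform_table(predictors, transforms, data)
  spec <- structure(
    list(predictors = predictors, transform = tt$transform,
         offset = tt$offset, include_treatment = include_treatment,
         standardize = standardize, center = NULL, scale = NULL,
         binary = NULL, ref_arm = "MTX_DN"),
    class = "design_spec")

  cols <- lapply(predictors, function(v) {
    apply_transform(data[[v]], tt$transform[[v]], tt$offset[[v]])
  })
  x <- do.call(cbind, cols)
  colnames(x) <- predictors
  spec$binary <- predictors[vapply(predictors, function(v) {
    all(data[[v]] %in% c(0, 1))
  }, logical(1))]
  cont <- setdiff(predictors, spec$binary)
  zv <- colnames(x)[apply(x, 2, function(col) stats::var(col) == 0)]
  if (length(zv)) {
    abort(sprintf("Design column '%s' has zero variance.", zv[1]))
  }
  if (standardize && length(cont)) {
    spec$center <- colMeans(x[, cont, drop = FALSE])
    spec$scale <- apply(x[, cont, drop = FALSE], 2, stats::sd)
    x[, cont] <- sweep(sweep(x[, cont, drop = FALSE], 2, spec$center),
                       2, spec$scale, "/")
  }
  if (include_treatment) {
    x <- cbind(x, arm_dummies(data$arm))
  }
  rownames(x) <- data$patient_id %||% as.character(seq_len(nrow(data)))
  spec$x <- x
  spec
}

arm_dummies <- function(arm) {
  lv <- arm_levels()
  unseen <- setdiff(unique(arm), lv)
  if (length(unseen)) {
    abort(sprintf("Unseen treatment arm label '%s'.", unseen[1]))
  }
  d <- matrix(0, nrow = length(arm), ncol = 3,
              dimnames = list(NULL, paste0("arm_", lv[-1])))
  for (a in lv[-1]) d[arm == a, paste0("arm_", a)] <- 1
  d
}

#' Project new patients onto a fitted design-matrix scale
#'
#' Applies the transformations and standardization parameters stored in a
#' `design_spec` to new rows, so that training and prediction use the exact
#' same scale. Optionally overrides the treatment arm, which is how
#' counterfactual predictions are formed.
#'
#' @param spec A `design_spec` from [build_design_matrix()].
#' @param data New patient rows with the same covariate columns.
#' @param arm Optional replacement arm (length 1 or `nrow(data)`) used
#'   instead of `data$arm` when encoding the treatment dummies.
#' @return Numeric matrix with the same columns as the training matrix.
#' @export
project_design <- function(spec, data, arm = NULL) {
  missing_cols <- setdiff(spec$predictors, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Predictor column '%s' not found in data.", missing_cols[1]))
  }
  cols <- lapply(spec$predictors, function(v) {
    apply_transform(data[[v]], spec$transform[[v]], spec$offset[[v]])
  })
  x <- do.call(cbind, cols)
  colnames(x) <- spec$predictors
  cont <- names(spec$center %||% numeric())
  if (length(cont)) {
    x[, cont] <- sweep(sweep(x[, cont, drop = FALSE], 2, spec$center),
                       2, spec$scale, "/")
  }
  if (spec$include_treatment) {
    a <- arm %||% data$arm
    if (length(a) == 1L) a <- rep(a, nrow(data))
    x <- cbind(x, arm_dummies(a))
  }
  rownames(x) <- data$patient_id %||% as.character(seq_len(nrow(data)))
  x
}
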