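#' Select relevant baseline predictors by elastic net across cohort subgroups
#'
#' Runs elastic-net selection with cross-validated penalty (at
#' `lambda_1se`) in four fits: the full cohort (with the three treatment
#' dummies as penalized covariates), the tofacitinib subgroup across both
#' strata (with a DN/DF stratum indicator), the methotrexate subgroup, and
#' the etanercept subgroup. A predictor is selected in a fit when its
#' coefficient is nonzero at `lambda_1se`; predictors selected in any fit
#' form the final union. Treatment dummies and the stratum indicator are
#' design variables, never eligible for selection. Candidates that are
#' constant within a subgroup (e.g. TNFi history among DMARD-naive patients)
#' are dropped from that fit only.
#'
#' @param cohort Cohort data frame with `arm`, `stratum`, the candidate
#'   predictor columns and the outcome.
#' @param candidates Character vector of candidate predictor columns.
#' @param outcome Binary outcome column name.
#' @param transforms Optional [screen_transforms()] result applied when
#'   building each design matrix.
#' @param alpha Elastic-net mixing for selection (default 0.5).
#' @param nfolds CV folds (`NULL` = leave-one-out).
#' @param ... Passed to [cv_path()].
#' @return A `selection_report`: tibble `provenance` (predictor x fit),
#'   character `union`, and the per-fit `cv_path`s and selected sets.
#' @export
select_union <- function(cohort, candidates, outcome = "mda_week16",
                         transforms = NULL, alpha = 0.5, nfolds = NULL, ...) {
  fits <- list(
    full_cohort = list(rows = rep(TRUE, nrow(cohort)),
                       treatment = TRUE, stratum_ind = FALSE),
    tofacitinib = list(rows = cohort$arm %in% c("TOFA_DN", "TOFA_DF"),
                       treatment = FALSE, stratum_ind = TRUE),
    methotrexate = list(rows = cohort$arm == "MTX_DN",
                        treatment = FALSE, stratum_ind = FALSE),
    etanercept = list(rows = cohort$arm == "ETN_DF",
                      treatment = FALSE, stratum_ind = FALSE))
  results <- lapply(names(fits), function(fname) {
    f <- fits[[fname]]
    sub <- cohort[f$rows, , drop = FALSE]
    y <- sub[[outcome]]
    if (length(unique(y)) < 2L) {
      warn(sprintf("Subgroup '%s' has a single outcome class; fit skipped.",
                   fname))
      return(list(name = fname, skipped = TRUE, selected = character()))
    }
    usable <- candidates[vapply(candidates, function(v) {
      stats::var(as.numeric(sub[[v]])) > 0
    }, logical(1))]
    dropped <- setdiff(candidates, usable)
    sub <- dplyr::mutate(sub, stratum_df = as.numeric(.data$stratum == "DF"))
    preds <- c(usable, if (f$stratum_ind &&
                           stats::var(sub$stratum_df) > 0) "stratum_df")
    dm <- build_design_matrix(sub, preds, transforms = transforms,
                              include_treatment = f$treatment)
    cvp <- cv_path(dm$x, y, alpha = alpha, nfolds = nfolds, ...)
    fit <- fit_at(cvp, "lambda_1se")
    nz <- names(fit$coefficients)[fit$coefficients != 0]
    list(name = fname, skipped = FALSE,
         selected = intersect(nz, usable), dropped = dropped,
         cv = cvp, fit = fit, n = nrow(sub))
  })
  names(results) <- names(fits)
  sel_sets <- lapply(results, `[[`, "selected")
  union_set <- candidates[candidates %in% unique(unlist(sel_sets))]
  if (!length(union_set)) {
    abort(paste("No predictor was selected in any fit; inspect the CV paths",
                "(lambda_1se chose the null model everywhere)."))
  }
  provenance <- tibble::tibble(predictor = union_set)
  for (fname in names(fits)) {
    provenance[[fname]] <- union_set %in% sel_sets[[fname]]
  }
  structure(list(union = union_set, provenance = provenance,
                 fits = results, candidates = candidates, alpha = alpha),
            class = "selection_report")
}

#' @exportS3Method
print.selection_report <- function(x, ...) {
  cat(sprintf("Elastic-net predictor selection (alpha = %g)\n", x$alpha))
  cat(sprintf("  union of %d predictor(s): %s\n", length(x$union),
              paste(x$union, collapse = ", ")))
  print(x$provenance)
  invisible(x)
}

#' @exportS3Method
tidy.selection_report <- function(x, ...) {
  tidyr::pivot_longer(x$provenance, -"predictor", names_to = "fit",
                      values_to = "selected")
}

#' @exportS3Method
glance.selection_report <- function(x, ...) {
  tibble::tibble(
    n_candidates = length(x$candidates), n_selected = length(x$union),
    alpha = x$alpha,
    fits_run = sum(!vapply(x$fits, `[[`, logical(1), "skipped")))
}
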