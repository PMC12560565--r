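#' Column dictionary for cohort tables
#'
#' The patient-level table the pipeline consumes: identifiers, stratum and
#' arm, the 16 baseline covariates, week-16 MDA components (suffix `_w16`)
#' and the derived outcome columns.
#'
#' @return Tibble with `column`, `type`, `description`.
#' @export
cohort_column_dictionary <- function() {
  tibble::tribble(
    ~column, ~type, ~description,
    "patient_id", "character", "Unique patient identifier",
    "stratum", "character", "DN (DMARD-naive) or DF (csDMARD failure)",
    "arm", "character", "MTX_DN, TOFA_DN, ETN_DF or TOFA_DF",
    "haq", "numeric", "HAQ disability index, 0-3",
    "tjc68", "integer", "Tender joint count (68 joints)",
    "sjc66", "integer", "Swollen joint count (66 joints)",
    "lei", "integer", "Leeds Enthesitis Index, 0-6",
    "vas_physician_global", "numeric", "Physician global VAS, 0-100 mm",
    "vas_pain", "numeric", "Pain VAS, 0-100 mm",
    "vas_patient_global", "numeric", "Patient global VAS, 0-100 mm",
    "bsa", "numeric", "Psoriasis body surface area, %",
    "crp", "numeric", "C-reactive protein, mg/L",
    "bmi", "numeric", "Body mass index",
    "age", "numeric", "Age, years",
    "sex", "binary", "0/1",
    "disease_duration", "numeric", "Disease duration, years",
    "tnfi_history", "binary", "Previous TNFi use (DF patients only)",
    "nail_psoriasis", "binary", "Nail psoriasis present",
    "dactylitis", "binary", "Dactylitis present",
    "*_w16", "numeric", "Week-16 value of an MDA component",
    "mda_week16", "binary", "Week-16 MDA responder outcome",
    "mda_criteria_met", "integer", "Number of MDA criteria met (0-7)",
    "mda_imputed", "logical", "Examination carried back from a later visit")
}

#' Write / read a cohort table as CSV
#'
#' UTF-8, comma-separated, header row, missing values as empty cells.
#' Reading validates the schema against [cohort_column_dictionary()]:
#' missing required columns and out-of-range values raise line-numbered
#' errors; unknown columns only warn.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `read_cohort` returns a tibble; `write_cohort` its input,
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- tibble::as_tibble(
    utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE))
  required <- c("patient_id", "stratum", "arm")
  miss <- setdiff(required, names(cohort))
  if (length(miss)) {
    abort(sprintf("Cohort file is missing required column '%s'.", miss[1]))
  }
  dict <- cohort_column_dictionary()
  known <- c(setdiff(dict$column, "*_w16"),
             paste0(names(mda_thresholds()), "_w16"),
             "true_eta", "true_prob", "is_mda", "stratum_df")
  unknown <- setdiff(names(cohort), known)
  if (length(unknown)) {
    warn(sprintf("Unknown cohort column(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  bad_arm <- which(!cohort$arm %in% arm_levels())
  if (length(bad_arm)) {
    abort(sprintf("Line %d: unknown arm label '%s'.",
                  bad_arm[1] + 1L, cohort$arm[bad_arm[1]]))
  }
  bad_str <- which(cohort$stratum != stratum_of_arm(cohort$arm))
  if (length(bad_str)) {
    abort(sprintf("Line %d: stratum '%s' inconsistent with arm '%s'.",
                  bad_str[1] + 1L, cohort$stratum[bad_str[1]],
                  cohort$arm[bad_str[1]]))
  }
  ranges <- mda_component_ranges()
  for (v in intersect(names(ranges), names(cohort))) {
    bad <- which(!is.na(cohort[[v]]) &
                   (cohort[[v]] < ranges[[v]][1] | cohort[[v]] > ranges[[v]][2]))
    if (length(bad)) {
      abort(sprintf("Line %d: column '%s' value %g out of range [%g, %g].",
                    bad[1] + 1L, v, cohort[[v]][bad[1]],
                    ranges[[v]][1], ranges[[v]][2]))
    }
  }
  cohort
}

#' Export / import a fitted strategy model as JSON
#'
#' The JSON carries the strategy tag, intercepts and coefficient maps,
#' penalty settings, transformation and standardization parameters —
#' everything needed to reproduce predictions exactly on new data.
#'
#' @param model A fitted `homogeneous_model`, `risk_model` or
#'   `effect_model`.
#' @param path File path.
#' @return `import_model` returns the reconstructed model object.
#' @export
export_model <- function(model, path) {
  payload <- serialize_model(model)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(model)
}

serialize_penfit <- function(fit) {
  list(intercept = fit$intercept, coefficients = as.list(fit$coefficients),
       alpha = fit$alpha, lambda = fit$lambda,
       penalty_factor = as.numeric(fit$penalty_factor),
       objective = fit$objective, converged = fit$converged,
       n_iter = fit$n_iter, nobs = fit$nobs)
}

deserialize_penfit <- function(x) {
  new_penfit(x$intercept, unlist(x$coefficients), x$alpha, x$lambda,
             as.numeric(unlist(x$penalty_factor)), x$objective, x$converged,
             x$n_iter, x$nobs)
}

serialize_design <- function(d) {
  list(predictors = d$predictors, transform = as.list(d$transform),
       offset = as.list(d$offset), include_treatment = d$include_treatment,
       standardize = d$standardize,
       center = as.list(d$center %||% stats::setNames(numeric(), character())),
       scale = as.list(d$scale %||% stats::setNames(numeric(), character())),
       binary = as.list(d$binary %||% character()), ref_arm = d$ref_arm)
}

deserialize_design <- function(x) {
  structure(list(
    predictors = unlist(x$predictors), transform = unlist(x$transform),
    offset = unlist(x$offset), include_treatment = x$include_treatment,
    standardize = x$standardize,
    center = if (length(x$center)) unlist(x$center),
    scale = if (length(x$scale)) unlist(x$scale),
    binary = unlist(x$binary) %||% character(), ref_arm = x$ref_arm,
    x = NULL), class = "design_spec")
}

serialize_model <- function(model) {
  if (inherits(model, "homogeneous_model")) {
    list(strategy = "homogeneous", fit = serialize_penfit(model$fit),
         design = serialize_design(model$design),
         predictors = model$predictors, outcome = model$outcome)
  } else if (inherits(model, "risk_model")) {
    list(strategy = "risk", stage1 = serialize_penfit(model$stage1),
         stage1_design = serialize_design(model$stage1_design),
         lp_coefficients = as.list(model$lp_coefficients),
         lp_center = model$lp_center, lp_scale = model$lp_scale,
         stage2 = serialize_penfit(model$stage2),
         predictors = model$predictors, outcome = model$outcome)
  } else if (inherits(model, "effect_model")) {
    list(strategy = "effect", fit = serialize_penfit(model$fit),
         design = serialize_design(model$design),
         selected_interactions = model$selected_interactions,
         predictors = model$predictors, outcome = model$outcome)
  } else {
    abort("Unknown model class.")
  }
}

#' @rdname export_model
#' @export
import_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (x$strategy == "homogeneous") {
    structure(list(fit = deserialize_penfit(x$fit), cv = NULL,
                   design = deserialize_design(x$design),
                   predictors = unlist(x$predictors), outcome = x$outcome),
              class = c("homogeneous_model", "psa_model"))
  } else if (x$strategy == "risk") {
    structure(list(stage1 = deserialize_penfit(x$stage1), stage1_cv = NULL,
                   stage1_design = deserialize_design(x$stage1_design),
                   lp_coefficients = unlist(x$lp_coefficients),
                   lp_center = x$lp_center, lp_scale = x$lp_scale,
                   stage2 = deserialize_penfit(x$stage2), stage2_cv = NULL,
                   predictors = unlist(x$predictors), outcome = x$outcome),
              class = c("risk_model", "psa_model"))
  } else if (x$strategy == "effect") {
    si <- dplyr::bind_rows(lapply(x$selected_interactions, tibble::as_tibble))
    if (!nrow(si)) si <- tibble::tibble(predictor = character(),
                                        arm = character())
    structure(list(fit = deserialize_penfit(x$fit), cv = NULL,
                   design = deserialize_design(x$design),
                   selected_interactions = si,
                   predictors = unlist(x$predictors), outcome = x$outcome),
              class = c("effect_model", "psa_model"))
  } else {
    abort(sprintf("Unknown strategy tag '%s' in model file.", x$strategy))
  }
}

#' Write / read a simulation configuration as YAML
#'
#' Serializes a [cohort_config()] (with an optional seed recorded as run
#' metadata) so a simulated cohort can be reproduced exactly.
#'
#' @param config A `sim_config` object.
#' @param path File path (`.yaml` or `.yml`).
#' @param seed Optional seed to record alongside the configuration.
#' @return `read_sim_config` returns `list(config, seed)`.
#' @export
write_sim_config <- function(config, path, seed = NULL) {
  payload <- list(
    seed = seed,
    n_per_arm = config$n_per_arm,
    true_intercept = config$true_intercept,
    true_beta = as.list(config$true_beta),
    true_treatment_effects = as.list(config$true_treatment_effects),
    true_interactions = config$true_interactions,
    correlation = config$correlation,
    covariates = lapply(config$covariates, function(s) {
      list(name = s$name, kind = s$kind, dist = s$dist, params = s$params,
           df_params = s$df_params, integer = s$integer, range = s$range)
    }))
  yaml::write_yaml(payload, path, precision = 17)
  invisible(config)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  covs <- lapply(x$covariates, function(s) {
    covariate_spec(s$name, s$kind, s$dist, s$params, df_params = s$df_params,
                   integer = isTRUE(s$integer),
                   range = if (!is.null(s$range)) as.numeric(s$range))
  })
  names(covs) <- vapply(covs, `[[`, character(1), "name")
  cfg <- cohort_config(
    n_per_arm = x$n_per_arm, covariates = covs,
    true_intercept = x$true_intercept, true_beta = unlist(x$true_beta),
    true_treatment_effects = unlist(x$true_treatment_effects),
    true_interactions = x$true_interactions %||% list(),
    correlation = x$correlation)
  list(config = cfg, seed = x$seed)
}

#' Default candidate predictor list
#'
#' The 16 baseline covariates considered as candidate predictors, and the
#' subset screened for skewness-driven transformations (continuous and
#' count variables only).
#'
#' @return Character vector of column names.
#' @export
default_candidates <- function() names(default_covariate_specs())

#' @rdname default_candidates
#' @export
continuous_candidates <- function() {
  specs <- default_covariate_specs()
  names(specs)[vapply(specs, function(s) s$kind != "binary", logical(1))]
}

#' Run the full prediction pipeline
#'
#' Simulate (or take) a cohort, compute the MDA outcome, screen
#' transformations, select predictors by elastic net across subgroups, fit
#' the homogeneous, risk-modelling and effect-modelling strategies,
#' evaluate each by nested leave-one-out cross-validated AUC-ROC, and
#' summarize per-patient counterfactual treatment comparisons. When
#' `out_dir` is given, all artifacts (cohort CSV, selection report,
#' model JSON files, counterfactual and impact CSVs, ROC points,
#' evaluation summary, run report) are written there; outputs are
#' byte-reproducible given the same config and seed.
#'
#' @param config A [cohort_config()]; ignored when `cohort` is supplied.
#' @param seed Integer seed for simulation.
#' @param cohort Optional existing cohort data frame.
#' @param candidates Candidate predictor columns.
#' @param strategies Strategies to fit and evaluate.
#' @param nfolds CV folds for tuning (`NULL` = leave-one-out).
#' @param reselect Repeat predictor selection inside the outer
#'   evaluation loop?
#' @param out_dir Optional output directory.
#' @return A `psa_pipeline` list with the cohort, transforms, selection,
#'   models, evaluations, counterfactuals and impact tables.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1, cohort = NULL,
                         candidates = default_candidates(),
                         strategies = c("homogeneous", "risk", "effect"),
                         nfolds = NULL, reselect = FALSE, out_dir = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config, seed)
  transforms <- screen_transforms(
    cohort, intersect(candidates, continuous_candidates()))
  selection <- select_union(cohort, candidates, transforms = transforms,
                            nfolds = nfolds)
  models <- list()
  evals <- list()
  pairs <- list()
  impact <- list()
  for (s in strategies) {
    models[[s]] <- fit_strategy(s, cohort, selection$union, "mda_week16",
                                transforms, nfolds)
    evals[[s]] <- nested_loocv(cohort, s,
                               selected_predictors = selection$union,
                               candidates = candidates, reselect = reselect,
                               transforms = transforms,
                               nfolds_inner = nfolds)
    pairs[[s]] <- predict_counterfactuals(models[[s]], cohort)
    impact[[s]] <- summarize_impact(pairs[[s]])
  }
  result <- structure(
    list(cohort = cohort, seed = seed, config = config,
         transforms = transforms,
         selection = selection, models = models, evaluations = evals,
         counterfactuals = pairs, impact = impact),
    class = "psa_pipeline")
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_cohort(result$cohort, fp("cohort.csv"))
  if (!is.null(result$config)) {
    write_sim_config(result$config, fp("config.yaml"), seed = result$seed)
  }
  utils::write.csv(result$transforms, fp("transforms.csv"),
                   row.names = FALSE)
  utils::write.csv(result$selection$provenance, fp("selection.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = result$seed, union = result$selection$union,
         alpha = result$selection$alpha),
    fp("selection.json"), digits = NA, auto_unbox = TRUE, pretty = TRUE)
  eval_summary <- dplyr::bind_rows(lapply(result$evaluations, glance))
  utils::write.csv(eval_summary, fp("evaluation.csv"), row.names = FALSE)
  for (s in names(result$models)) {
    export_model(result$models[[s]], fp(sprintf("model_%s.json", s)))
    utils::write.csv(result$counterfactuals[[s]],
                     fp(sprintf("counterfactuals_%s.csv", s)),
                     row.names = FALSE)
    utils::write.csv(result$impact[[s]], fp(sprintf("impact_%s.csv", s)),
                     row.names = FALSE)
    utils::write.csv(result$evaluations[[s]]$roc_points,
                     fp(sprintf("roc_%s.csv", s)), row.names = FALSE)
  }
  writeLines(render_report(result), fp("report.md"))
  invisible(result)
}

render_report <- function(result) {
  eval_summary <- dplyr::bind_rows(lapply(result$evaluations, glance))
  c("# Treatment-response prediction pipeline report",
    "",
    sprintf("Seed: %d. Cohort: %d patients (%s).", result$seed,
            nrow(result$cohort),
            paste(sprintf("%s n=%d", names(table(result$cohort$arm)),
                          as.integer(table(result$cohort$arm))),
                  collapse = ", ")),
    sprintf("Overall MDA response rate: %.1f%%.",
            100 * mean(result$cohort$mda_week16)),
    "",
    "## Selected predictors",
    "",
    paste("Union:", paste(result$selection$union, collapse = ", ")),
    "",
    knit_table(result$selection$provenance),
    "",
    "## Model performance (nested LOOCV)",
    "",
    knit_table(eval_summary[c("strategy", "auc_outer", "auc_inner",
                              "final_lambda")]),
    "",
    "## Counterfactual impact per stratum",
    "",
    unlist(lapply(names(result$impact), function(s) {
      c(sprintf("### %s", s), "", knit_table(result$impact[[s]]), "")
    })))
}

knit_table <- function(df) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = 4, format = "g") else as.character(x)
  }
  body <- apply(as.data.frame(lapply(df, fmt)), 1, paste, collapse = " | ")
  c(paste("|", paste(names(df), collapse = " | "), "|"),
    paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
    paste("|", body, "|"))
}

#' @exportS3Method
print.psa_pipeline <- function(x, ...) {
  cat(sprintf("PsA treatment-response pipeline (n = %d, seed = %d)\n",
              nrow(x$cohort), x$seed))
  cat(sprintf("  selected predictors: %s\n",
              paste(x$selection$union, collapse = ", ")))
  for (s in names(x$evaluations)) {
    cat(sprintf("  %-12s outer AUC = %.3f\n", s, x$evaluations[[s]]$auc_outer))
  }
  invisible(x)
}
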