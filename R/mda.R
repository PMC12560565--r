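#' Minimal Disease Activity (MDA) criterion thresholds
#'
#' The seven MDA criteria for psoriatic arthritis, evaluated with inclusive
#' (`<=`) thresholds: tender joint count (68 joints) <= 1, swollen joint count
#' (66 joints) <= 1, psoriasis body surface area <= 3%, pain VAS <= 15 mm,
#' patient global activity VAS <= 20 mm, HAQ disability index <= 0.5, and
#' tender entheseal points (Leeds Enthesitis Index) <= 1. A patient is in MDA
#' when at least 5 of the 7 criteria are met.
#'
#' VAS thresholds assume a 0-100 mm scale; override the returned vector (e.g.
#' divide by 10) if scores were captured on a 0-10 cm dialect.
#'
#' @return Named numeric vector of the seven thresholds.
#' @export
mda_thresholds <- function() {
  c(tjc68 = 1, sjc66 = 1, bsa = 3, vas_pain = 15,
    vas_patient_global = 20, haq = 0.5, lei = 1)
}

mda_component_ranges <- function() {
  list(tjc68 = c(0, 68), sjc66 = c(0, 66), bsa = c(0, 100),
       vas_pain = c(0, 100), vas_patient_global = c(0, 100),
       haq = c(0, 3), lei = c(0, 6))
}

validate_mda_components <- function(data, fields = names(mda_thresholds())) {
  ranges <- mda_component_ranges()
  for (f in fields) {
    if (!f %in% names(data)) {
      abort(sprintf("MDA component column '%s' is missing.", f))
    }
    x <- data[[f]]
    if (anyNA(x)) {
      abort(sprintf("MDA component '%s' contains missing values.", f))
    }
    r <- ranges[[f]]
    if (any(x < r[1] | x > r[2])) {
      abort(sprintf("MDA component '%s' out of range [%g, %g].", f, r[1], r[2]))
    }
  }
  invisible(data)
}

mda_criteria_matrix <- function(data, thresholds = mda_thresholds()) {
  m <- vapply(names(thresholds), function(f) data[[f]] <= thresholds[[f]],
              logical(nrow(data)))
  matrix(m, nrow = nrow(data), dimnames = list(NULL, names(thresholds)))
}

#' Compute the MDA responder outcome from disease-activity components
#'
#' Evaluates the seven MDA criteria (see [mda_thresholds()]) on one row per
#' patient and classifies each patient as responder (`is_mda`) when at least
#' 5 criteria are met.
#'
#' @param data Data frame with one row per patient holding the component
#'   columns `tjc68`, `sjc66`, `bsa`, `vas_pain`, `vas_patient_global`,
#'   `haq`, `lei` (optionally with a common `suffix`, e.g. `"_w16"`).
#' @param suffix Optional suffix appended to every component column name.
#' @param thresholds Named vector of criterion thresholds.
#' @return `data` with columns `mda_criteria_met` (0-7), `is_mda` (logical),
#'   `mda_week16` (0/1, the modelling outcome), and `mda_imputed` (always
#'   `FALSE` here) appended, as a tibble.
#' @export
#' @examples
#' compute_mda(tibble::tibble(tjc68 = 0, sjc66 = 0, bsa = 0, vas_pain = 0,
#'   vas_patient_global = 0, haq = 0, lei = 0))
compute_mda <- function(data, suffix = "", thresholds = mda_thresholds()) {
  comp <- names(thresholds)
  cols <- paste0(comp, suffix)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("MDA component column '%s' is missing.", missing_cols[1]))
  }
  comps <- stats::setNames(data[cols], comp)
  validate_mda_components(comps)
  crit <- mda_criteria_matrix(comps, thresholds)
  out <- tibble::as_tibble(data)
  out$mda_criteria_met <- as.integer(rowSums(crit))
  out$is_mda <- out$mda_criteria_met >= 5L
  out$mda_week16 <- as.integer(out$is_mda)
  out$mda_imputed <- FALSE
  out
}

#' Compute MDA combining week-16 patient-reported outcomes with a later exam
#'
#' When the physical examination at the outcome visit is missing (e.g. a
#' missed visit), the patient-reported components from week 16 (`haq`,
#' `vas_pain`, `vas_patient_global`) are combined with the examination
#' components (`tjc68`, `sjc66`, `bsa`, `lei`) carried back from the first
#' subsequent visit. Fields present at week 16 always take precedence; rows
#' where any component was actually taken from the later visit are flagged
#' `mda_imputed = TRUE`.
#'
#' @param week16 Data frame of (possibly partial) week-16 components; missing
#'   fields may be absent columns or `NA` cells.
#' @param later_visit Data frame of components from the later visit, same
#'   number of rows.
#' @inheritParams compute_mda
#' @return Tibble of merged components with `mda_criteria_met`, `is_mda`
#'   and `mda_imputed`.
#' @export
compute_mda_with_fallback <- function(week16, later_visit,
                                      thresholds = mda_thresholds()) {
  if (nrow(week16) != nrow(later_visit)) {
    abort("week16 and later_visit must have the same number of rows.")
  }
  comp <- names(thresholds)
  get_col <- function(df, f) {
    if (f %in% names(df)) df[[f]] else rep(NA_real_, nrow(df))
  }
  merged <- tibble::as_tibble(lapply(stats::setNames(comp, comp), function(f) {
    dplyr::coalesce(get_col(week16, f), get_col(later_visit, f))
  }))
  for (f in comp) {
    if (anyNA(merged[[f]])) {
      abort(sprintf("MDA component '%s' missing from both sources.", f))
    }
  }
  miss16 <- vapply(comp, function(f) is.na(get_col(week16, f)),
                   logical(nrow(week16)))
  imputed <- rowSums(matrix(miss16, nrow = nrow(week16))) > 0
  out <- compute_mda(merged, thresholds = thresholds)
  out$mda_imputed <- imputed
  out
}
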