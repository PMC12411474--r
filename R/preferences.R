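#' Critical-preference thresholding
#'
#' Patients and clinicians rate each catalogue outcome from 1 (not
#' important) to 9 (very important); an outcome rated at or above the
#' threshold (default 7) is "critical" and enters the evidence analysis.
#'
#' @param ratings data.frame with columns `rater`, `outcome_id`, `score`.
#' @param threshold Criticality cut-point; a score `>= threshold` is
#'   critical.  Default 7.
#' @param max_critical Optional cap on the number of critical outcomes per
#'   rater; when exceeded the highest-rated outcomes are kept
#'   (ties broken by catalogue order).  Default `NULL` (no cap).
#' @return A named list of character vectors of critical `outcome_id`s,
#'   one per rater present in `ratings` (sorted).
#' @examples
#' r <- data.frame(rater = "patient",
#'                 outcome_id = c("adhd_symptoms", "seizures", "insomnia"),
#'                 score = c(9L, 7L, 6L))
#' mark_critical(r)$patient   # adhd_symptoms, seizures
#' @export
mark_critical <- function(ratings, threshold = 7, max_critical = NULL) {
  stopifnot(is.data.frame(ratings),
            all(c("rater", "outcome_id", "score") %in% names(ratings)))
  if (anyDuplicated(ratings[, c("rater", "outcome_id")]))
    stop("duplicate (rater, outcome) rating")
  if (anyNA(ratings$score)) {
    warning("missing rating scores treated as non-critical")
    ratings <- ratings[!is.na(ratings$score), , drop = FALSE]
  }
  out <- lapply(split(ratings, ratings$rater), function(df) {
    crit <- df[df$score >= threshold, , drop = FALSE]
    if (!is.null(max_critical) && nrow(crit) > max_critical)
      crit <- crit[order(-crit$score)[seq_len(max_critical)], , drop = FALSE]
    sort(unique(crit$outcome_id))
  })
  for (rt in names(out))
    if (!length(out[[rt]]))
      warning("rater '", rt, "' marked no outcome as critical")
  out
}

#' Combine patient and clinician critical sets
#'
#' The comprehensive rule keeps every outcome either rater deems critical
#' (set union); the conjoint rule keeps only outcomes both deem critical
#' (set intersection).  A conjoint combination can be empty when the two
#' raters agree on nothing, in which case no recommendation can be produced
#' downstream.
#'
#' @param patient_set,clinician_set Character vectors of critical outcome
#'   ids.
#' @param mode `"comprehensive"` (union) or `"conjoint"` (intersection).
#' @return Sorted character vector of outcome ids (possibly empty).
#' @export
combine_preferences <- function(patient_set, clinician_set,
                                mode = c("comprehensive", "conjoint")) {
  mode <- match.arg(mode)
  res <- if (mode == "comprehensive") union(patient_set, clinician_set)
         else intersect(patient_set, clinician_set)
  sort(unique(res))
}

#' Cohort preference summary
#'
#' Per-rater and per-combination counts over a cohort: mean critical-set
#' sizes and the number of distinct critical-preference combinations.
#' The inclusion-exclusion identity
#' `mean|patient| + mean|clinician| = mean|union| + mean|intersection|`
#' holds exactly on every cohort.
#'
#' @param cases List of [patient_case()] objects.
#' @param threshold Criticality threshold forwarded to [mark_critical()].
#' @return A list with `means` (named numeric: patient, clinician,
#'   comprehensive, conjoint), `distinct_combinations` (named integer for the
#'   two combination modes) and `sizes` (per-case data.frame).
#' @export
preference_summary <- function(cases, threshold = 7) {
  if (!length(cases)) stop("empty cohort")
  rows <- lapply(cases, function(cs) {
    crit <- suppressWarnings(mark_critical(cs$ratings, threshold))
    p <- crit$patient %||% character(0)
    c_ <- crit$clinician %||% character(0)
    list(case_id = cs$case_id, patient = p, clinician = c_,
         comprehensive = combine_preferences(p, c_, "comprehensive"),
         conjoint = combine_preferences(p, c_, "conjoint"))
  })
  sizes <- data.frame(
    case_id = vapply(rows, `[[`, character(1), "case_id"),
    patient = vapply(rows, function(r) length(r$patient), integer(1)),
    clinician = vapply(rows, function(r) length(r$clinician), integer(1)),
    comprehensive = vapply(rows, function(r) length(r$comprehensive), integer(1)),
    conjoint = vapply(rows, function(r) length(r$conjoint), integer(1)))
  key <- function(field) vapply(rows, function(r)
    paste(r[[field]], collapse = "+"), character(1))
  list(
    means = c(patient = mean(sizes$patient),
              clinician = mean(sizes$clinician),
              comprehensive = mean(sizes$comprehensive),
              conjoint = mean(sizes$conjoint)),
    distinct_combinations = c(
      comprehensive = length(unique(key("comprehensive"))),
      conjoint = length(unique(key("conjoint")))),
    sizes = sizes)
}
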