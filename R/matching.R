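#' Pooling levels
#'
#' The engine pools trials at four levels.  L1 requires a stringent
#' patient-trial match and runs one meta-analysis per drug and dose; as the
#' level rises the match criteria relax and the grouping broadens:
#'
#' | level | eligibility strictness | grouping    |
#' |-------|------------------------|-------------|
#' | L1    | strict                 | drug + dose |
#' | L2    | strict                 | drug        |
#' | L3    | relaxed                | drug        |
#' | L4    | minimal                | drug class  |
#'
#' `strict` enforces the full criteria set (age range, sex, excluded
#' comorbidities and co-treatments, severity threshold); `relaxed` enforces
#' the child/adolescent-vs-adult age band plus excluded comorbidities;
#' `minimal` the age band only.  Each rung can be overridden.
#'
#' @param level `"L1"`..`"L4"`.
#' @param strictness,grouping Optional overrides of the packaged ladder.
#' @return A `pooling_level` object.
#' @export
pooling_level <- function(level = c("L1", "L2", "L3", "L4"),
                          strictness = NULL, grouping = NULL) {
  level <- match.arg(level)
  ladder <- list(L1 = c("strict", "drug+dose"), L2 = c("strict", "drug"),
                 L3 = c("relaxed", "drug"), L4 = c("minimal", "drug_class"))
  strictness <- match.arg(strictness %||% ladder[[level]][1],
                          c("strict", "relaxed", "minimal"))
  grouping <- match.arg(grouping %||% ladder[[level]][2],
                        c("drug+dose", "drug", "drug_class"))
  structure(list(level = level, strictness = strictness,
                 grouping = grouping), class = "pooling_level")
}

age_band <- function(age) if (age < 18) "pediatric" else "adult"

trial_age_band <- function(elig) {
  if (elig$age_max < 18) "pediatric"
  else if (elig$age_min >= 18) "adult"
  else "mixed"
}

#' Patient-trial eligibility
#'
#' Checks whether a patient would have met a trial's inclusion and exclusion
#' criteria.  Eligibility is monotone in strictness: a patient eligible
#' under `strict` is eligible under `relaxed` and `minimal`.
#'
#' @param patient A [patient_profile()].
#' @param trial A [trial_record()].
#' @param strictness `"strict"`, `"relaxed"` or `"minimal"`.
#' @return A list with `eligible` (logical) and `reasons` (character vector
#'   naming every failed criterion; empty when eligible).
#' @examples
#' tr <- trial_record("t1", "methylphenidate", "stimulant-MPH",
#'                    eligibility_criteria(6, 17),
#'                    list(arm_summary("intervention", "methylphenidate", 50),
#'                         arm_summary("placebo", "placebo", 50)))
#' check_eligibility(patient_profile(12, "male"), tr, "strict")$eligible
#' @export
check_eligibility <- function(patient, trial,
                              strictness = c("strict", "relaxed", "minimal")) {
  strictness <- match.arg(strictness)
  e <- trial$eligibility
  reasons <- character(0)
  band <- trial_age_band(e)
  if (band != "mixed" && age_band(patient$age) != band)
    reasons <- c(reasons, sprintf("age band mismatch (%s patient, %s trial)",
                                  age_band(patient$age), band))
  if (strictness %in% c("strict", "relaxed")) {
    hit <- intersect(patient$comorbidities, e$excluded_comorbidities)
    if (length(hit))
      reasons <- c(reasons, paste("excluded comorbidity:",
                                  paste(hit, collapse = ", ")))
  }
  if (strictness == "strict") {
    if (patient$age < e$age_min || patient$age > e$age_max)
      reasons <- c(reasons, sprintf("age %g outside trial range %g-%g",
                                    patient$age, e$age_min, e$age_max))
    if (!patient$sex %in% e$sexes_allowed)
      reasons <- c(reasons, paste("sex not eligible:", patient$sex))
    hit <- intersect(patient$current_treatments, e$excluded_cotreatments)
    if (length(hit))
      reasons <- c(reasons, paste("excluded co-treatment:",
                                  paste(hit, collapse = ", ")))
    if (!is.null(e$min_severity) && !is.na(e$min_severity)) {
      if (is.na(patient$symptom_severity)) {
        # patient record lacks the trial's severity scale: criterion skipped
        warning("severity criterion skipped for trial '", trial$trial_id,
                "': patient has no severity score", call. = FALSE)
      } else if (patient$symptom_severity < e$min_severity) {
        reasons <- c(reasons, sprintf("severity %g below trial minimum %g",
                                      patient$symptom_severity, e$min_severity))
      }
    }
  }
  list(eligible = !length(reasons), reasons = reasons)
}

dose_bucket <- function(dose)
  if (is.na(dose)) "flexible" else format(dose, trim = TRUE)

group_key <- function(trial, grouping)
  switch(grouping,
         "drug+dose" = paste0(trial$drug, "@", dose_bucket(trial$dose_mg_per_day)),
         "drug" = trial$drug,
         "drug_class" = trial$drug_class)

#' Select and group eligible trials
#'
#' Filters the corpus to trials the patient is eligible for at the level's
#' strictness and groups them by the level's key: `(drug, dose)` at L1,
#' drug at L2/L3, drug class at L4.  Groups with no trials are omitted.
#'
#' @inheritParams check_eligibility
#' @param corpus An `evidence_corpus`.
#' @param level A [pooling_level()] (or level string).
#' @return Named list of `trial_record` lists keyed by group.
#' @export
select_trials <- function(patient, corpus, level = pooling_level("L3")) {
  if (is.character(level)) level <- pooling_level(level)
  elig <- vapply(corpus$trials, function(tr)
    suppressWarnings(check_eligibility(patient, tr, level$strictness)$eligible),
    logical(1))
  kept <- corpus$trials[elig]
  if (!length(kept)) return(structure(list(), names = character(0)))
  keys <- vapply(kept, group_key, character(1), grouping = level$grouping)
  groups <- split(kept, keys)
  groups[order(names(groups))]
}

#' Assemble a PICO question
#'
#' P is the patient, I the eligible intervention groups, C always placebo,
#' O the combined critical-preference set.  An empty critical set yields a
#' typed `"no-critical-preferences"` marker instead of an error; an empty
#' intervention set propagates as "no recommendation possible".
#'
#' @inheritParams select_trials
#' @param critical_set Character vector of critical outcome ids.
#' @return A `pico_question` with `patient`, `interventions` (group keys),
#'   `groups`, `comparator = "placebo"`, `outcomes` and `status` (one of
#'   `"ok"`, `"no-critical-preferences"`, `"no-eligible-trials"`).
#' @export
build_pico <- function(patient, critical_set, corpus,
                       level = pooling_level("L3")) {
  if (is.character(level)) level <- pooling_level(level)
  if (!length(critical_set))
    return(structure(list(patient = patient, interventions = character(0),
                          groups = list(), comparator = "placebo",
                          outcomes = character(0), level = level,
                          status = "no-critical-preferences"),
                     class = "pico_question"))
  groups <- select_trials(patient, corpus, level)
  structure(list(patient = patient, interventions = names(groups),
                 groups = groups, comparator = "placebo",
                 outcomes = sort(critical_set), level = level,
                 status = if (length(groups)) "ok" else "no-eligible-trials"),
            class = "pico_question")
}
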