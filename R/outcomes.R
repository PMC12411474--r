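#' Outcome catalogue
#'
#' The engine analyses treatment effects over a catalogue of ratable
#' treatment outcomes ("preferences").  Each entry declares its key, a
#' human-readable label, whether it measures efficacy, safety or treatment
#' discontinuation, its measurement scale, and which direction of effect is
#' beneficial.  The packaged default has 18 entries: the named efficacy and
#' safety goals elicited in the clinical studies plus provisional
#' placeholders completing the set (the full published list is not public).
#'
#' @param entries A data.frame with columns `outcome_id`, `label`, `kind`
#'   (`"efficacy"`, `"safety"` or `"discontinuation"`), `scale`
#'   (`"continuous"` or `"dichotomous"`), and `benefit_direction`
#'   (`"decrease-is-good"`/`"increase-is-good"` for continuous scales,
#'   `"event-is-harm"`/`"event-is-good"` for dichotomous ones).
#' @return A validated `outcome_catalogue` data.frame.
#' @examples
#' cat18 <- default_outcome_catalogue()
#' nrow(cat18)      # 18
#' table(cat18$kind)
#' @export
outcome_catalogue <- function(entries) {
  stopifnot(is.data.frame(entries))
  req <- c("outcome_id", "label", "kind", "scale", "benefit_direction")
  miss <- setdiff(req, names(entries))
  if (length(miss))
    stop("outcome catalogue is missing columns: ", paste(miss, collapse = ", "))
  entries <- entries[, req]
  if (anyDuplicated(entries$outcome_id))
    stop("duplicate outcome_id in catalogue: ",
         paste(unique(entries$outcome_id[duplicated(entries$outcome_id)]),
               collapse = ", "))
  if (!all(entries$kind %in% c("efficacy", "safety", "discontinuation")))
    stop("outcome kind must be efficacy, safety or discontinuation")
  if (!all(entries$scale %in% c("continuous", "dichotomous")))
    stop("outcome scale must be continuous or dichotomous")
  ok_dir <- ifelse(entries$scale == "continuous",
                   entries$benefit_direction %in%
                     c("decrease-is-good", "increase-is-good"),
                   entries$benefit_direction %in%
                     c("event-is-harm", "event-is-good"))
  if (!all(ok_dir))
    stop("benefit_direction inconsistent with scale for: ",
         paste(entries$outcome_id[!ok_dir], collapse = ", "))
  # discontinuation outcomes are counts of patients leaving treatment
  bad_disc <- entries$kind == "discontinuation" & entries$scale != "dichotomous"
  if (any(bad_disc))
    stop("discontinuation outcomes must be dichotomous: ",
         paste(entries$outcome_id[bad_disc], collapse = ", "))
  rownames(entries) <- NULL
  class(entries) <- c("outcome_catalogue", "data.frame")
  entries
}

#' @rdname outcome_catalogue
#' @export
default_outcome_catalogue <- function() {
  cont <- function(id, label, dir = "decrease-is-good")
    data.frame(outcome_id = id, label = label, kind = "efficacy",
               scale = "continuous", benefit_direction = dir)
  saf <- function(id, label)
    data.frame(outcome_id = id, label = label, kind = "safety",
               scale = "dichotomous", benefit_direction = "event-is-harm")
  entries <- rbind(
    cont("adhd_symptoms",       "Improvement of ADHD symptoms"),
    cont("clinical_impression", "Clinical global impression"),
    cont("quality_of_life",     "Quality of life", "increase-is-good"),
    cont("academic_performance","Academic performance", "increase-is-good"),
    cont("executive_function",  "Executive function", "increase-is-good"),
    cont("social_functioning",  "Social functioning", "increase-is-good"),
    saf("seizures",             "Seizures"),
    saf("vasovagal_syncope",    "Vasovagal syncope"),
    saf("appetite_decrease",    "Appetite decrease"),
    saf("insomnia",             "Insomnia"),
    saf("tics",                 "Tics"),
    saf("anxiety_worsening",    "Worsening of anxiety"),
    saf("irritability",         "Irritability"),
    saf("blood_pressure_increase", "Blood pressure increase"),
    saf("heart_rate_increase",  "Heart rate increase"),
    saf("abdominal_pain",       "Abdominal pain"),
    saf("growth_retardation",   "Growth retardation"),
    data.frame(outcome_id = "treatment_discontinuation",
               label = "Treatment discontinuation",
               kind = "discontinuation", scale = "dichotomous",
               benefit_direction = "event-is-harm")
  )
  outcome_catalogue(entries)
}
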