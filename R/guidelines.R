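#' Guideline rulesets
#'
#' Comparator recommender systems are encoded as declarative, editable
#' first-match-wins rulesets: an ordered list of rules, each with a
#' condition over the patient profile (age bounds, comorbidity or
#' adverse-event-history membership) and a recommended drug set.  The last
#' rule of a valid ruleset is a catch-all so that every patient matches.
#' The packaged encodings (AAP, NICE, SHS, CADDRA, AADPA) approximate the
#' first/second-line pharmacotherapy of the respective ADHD guidelines:
#' a default first-line set plus a non-stimulant second line for patients
#' with a stimulant contraindication (encoded provisionally as psychosis or
#' cardiovascular comorbidity, or a prior serious adverse event to a
#' stimulant).  They ship as JSON under
#' `system.file("extdata/guidelines", package = "metarec")`.
#'
#' @param path Path to a ruleset JSON file.
#' @return A `guideline_ruleset`.
#' @examples
#' gl <- default_guidelines()
#' apply_guideline(patient_profile(12, "male"), gl$NICE)
#' @export
read_guideline <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path)
  if (is.null(doc$guideline_id) || is.null(doc$rules))
    stop("'", path, "': not a guideline ruleset")
  rules <- lapply(doc$rules, function(r)
    list(label = r$label %||% "",
         when = lapply(r$when %||% list(), unlist),
         drugs = chr0(r$drugs)))
  last <- rules[[length(rules)]]
  if (length(last$when))
    stop("'", path, "': last rule must be a catch-all (empty condition)")
  structure(list(guideline_id = doc$guideline_id, rules = rules),
            class = "guideline_ruleset")
}

#' @rdname read_guideline
#' @export
default_guidelines <- function() {
  dir <- system.file("extdata", "guidelines", package = "metarec")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  rs <- lapply(files, read_guideline)
  names(rs) <- vapply(rs, `[[`, character(1), "guideline_id")
  rs[order(names(rs))]
}

rule_matches <- function(patient, when) {
  if (!length(when)) return(TRUE)
  ok <- TRUE
  if (!is.null(when$age_min)) ok <- ok && patient$age >= as.numeric(when$age_min)
  if (!is.null(when$age_max)) ok <- ok && patient$age <= as.numeric(when$age_max)
  if (!is.null(when$comorbidity_any))
    ok <- ok && length(intersect(patient$comorbidities, when$comorbidity_any)) > 0
  if (!is.null(when$serious_ae_any))
    ok <- ok && length(intersect(patient$history_serious_ae,
                                 when$serious_ae_any)) > 0
  if (!is.null(when$failure_any))
    ok <- ok && length(intersect(patient$history_failures,
                                 when$failure_any)) > 0
  ok
}

#' Apply a guideline ruleset to a patient
#'
#' Pure function of the profile: walks the rules in order and returns the
#' drug set of the first matching rule.  An empty set is only produced by an
#' explicit no-treatment rule; a ruleset with no matching rule is an error
#' (rulesets must be total).
#'
#' @param patient A [patient_profile()].
#' @param ruleset A [read_guideline()] ruleset.
#' @return Sorted character vector of drug codes.
#' @export
apply_guideline <- function(patient, ruleset) {
  for (r in ruleset$rules)
    if (rule_matches(patient, r$when)) return(sort(unique(r$drugs)))
  stop("ruleset '", ruleset$guideline_id,
       "' is not total: no rule matched the patient")
}

#' @rdname apply_guideline
#' @param cases List of [patient_case()] objects.
#' @export
guideline_output <- function(cases, ruleset) {
  sets <- lapply(cases, function(cs) apply_guideline(cs$profile, ruleset))
  names(sets) <- vapply(cases, `[[`, character(1), "case_id")
  system_output(ruleset$guideline_id, sets)
}
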