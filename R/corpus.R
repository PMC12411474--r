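#' Evidence-corpus building blocks
#'
#' Constructors for the structured trial records the engine consumes: a
#' trial carries its eligibility criteria, two or more arms (exactly one
#' placebo), arm-level outcome summaries (change-score mean/sd for
#' continuous outcomes, event counts for dichotomous ones) and a trial-level
#' risk-of-bias rating.
#'
#' @param age_min,age_max Eligible age range in whole years.
#' @param sexes_allowed Subset of `c("male", "female")`.
#' @param required_diagnosis Diagnosis code (default `"adhd"`).
#' @param excluded_comorbidities,excluded_cotreatments Condition / drug codes
#'   that exclude a patient.
#' @param min_severity Minimum symptom severity on the trial's scale, or
#'   `NULL` when the trial has no severity threshold.
#' @param other_flags Named logical vector of additional criteria flags.
#' @return An object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(age_min, age_max,
                                 sexes_allowed = c("male", "female"),
                                 required_diagnosis = "adhd",
                                 excluded_comorbidities = character(0),
                                 excluded_cotreatments = character(0),
                                 min_severity = NULL,
                                 other_flags = logical(0)) {
  stopifnot(is.numeric(age_min), is.numeric(age_max))
  if (age_min > age_max) stop("age_min must be <= age_max")
  if (!all(sexes_allowed %in% c("male", "female")) || !length(sexes_allowed))
    stop("sexes_allowed must be a non-empty subset of male/female")
  structure(list(
    age_min = as.numeric(age_min), age_max = as.numeric(age_max),
    sexes_allowed = unique(sexes_allowed),
    required_diagnosis = required_diagnosis,
    excluded_comorbidities = unique(as.character(excluded_comorbidities)),
    excluded_cotreatments = unique(as.character(excluded_cotreatments)),
    min_severity = min_severity,
    other_flags = other_flags
  ), class = "eligibility_criteria")
}

#' @rdname eligibility_criteria
#' @param arm_role `"intervention"` or `"placebo"`.
#' @param drug Drug code (`"placebo"` for placebo arms).
#' @param dose_mg_per_day Assigned daily dose, `NA` for flexible dosing.
#' @param n Number of randomized participants in the arm.
#' @param continuous Named list of `list(mean=, sd=)` change-score summaries
#'   keyed by outcome_id.
#' @param events Named integer vector of event counts keyed by outcome_id.
#' @export
arm_summary <- function(arm_role, drug, n, dose_mg_per_day = NA_real_,
                        continuous = list(), events = integer(0)) {
  arm_role <- match.arg(arm_role, c("intervention", "placebo"))
  if (arm_role == "placebo" && drug != "placebo")
    stop("placebo arm must carry drug code 'placebo'")
  if (arm_role == "intervention" && drug == "placebo")
    stop("intervention arm cannot carry drug code 'placebo'")
  if (n < 1) stop("arm n must be >= 1")
  for (oid in names(continuous)) {
    cs <- continuous[[oid]]
    if (!is.finite(cs$mean) || !is.finite(cs$sd) || cs$sd <= 0)
      stop("continuous summary for '", oid, "' needs finite mean and sd > 0")
  }
  if (length(events)) {
    ev <- unlist(events)
    if (any(ev < 0) || any(ev > n))
      stop("event counts must satisfy 0 <= events <= n")
  }
  structure(list(arm_role = arm_role, drug = drug,
                 dose_mg_per_day = as.numeric(dose_mg_per_day),
                 n = as.integer(n),
                 continuous = continuous,
                 events = as.list(events)),
            class = "arm_summary")
}

#' @rdname eligibility_criteria
#' @param trial_id Unique trial identifier.
#' @param drug_class Pharmacological class code used for L4 grouping.
#' @param eligibility An [eligibility_criteria()] object.
#' @param arms List of [arm_summary()] objects, at least one intervention and
#'   exactly one placebo arm.
#' @param risk_of_bias `"low"`, `"some-concerns"` or `"high"`.
#' @param year Publication year.
#' @param endpoint_scores `TRUE` when continuous summaries are endpoint
#'   rather than change-from-baseline scores.
#' @export
trial_record <- function(trial_id, drug, drug_class, eligibility, arms,
                         risk_of_bias = "low", year = 2020L,
                         dose_mg_per_day = NA_real_,
                         endpoint_scores = FALSE) {
  risk_of_bias <- match.arg(risk_of_bias, c("low", "some-concerns", "high"))
  stopifnot(inherits(eligibility, "eligibility_criteria"))
  roles <- vapply(arms, function(a) a$arm_role, character(1))
  if (sum(roles == "placebo") != 1)
    stop("trial '", trial_id, "' must have exactly one placebo arm")
  if (!any(roles == "intervention"))
    stop("trial '", trial_id, "' must have an intervention arm")
  structure(list(trial_id = trial_id, drug = drug,
                 dose_mg_per_day = as.numeric(dose_mg_per_day),
                 drug_class = drug_class, eligibility = eligibility,
                 arms = arms, risk_of_bias = risk_of_bias,
                 year = as.integer(year),
                 endpoint_scores = isTRUE(endpoint_scores)),
            class = "trial_record")
}

#' @rdname eligibility_criteria
#' @param outcomes An [outcome_catalogue()].
#' @param trials List of [trial_record()] objects.
#' @param drugs Drug registry data.frame (see [default_drug_registry()]).
#' @export
evidence_corpus <- function(trials, outcomes = default_outcome_catalogue(),
                            drugs = default_drug_registry()) {
  obj <- structure(list(outcomes = outcomes, trials = trials, drugs = drugs),
                   class = "evidence_corpus")
  rep <- validate_corpus(obj)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs))
    stop("invalid corpus:\n", paste0("  - [", errs$record, "] ",
                                     errs$message, collapse = "\n"))
  obj
}

#' @export
print.evidence_corpus <- function(x, ...) {
  cat("evidence corpus:", length(x$trials), "trials,",
      nrow(x$outcomes), "catalogue outcomes,",
      nrow(x$drugs), "registered drugs\n")
  invisible(x)
}

#' Patient records
#'
#' A patient case couples a demographic/clinical profile with two complete
#' sets of 1-9 preference ratings over the outcome catalogue, one from the
#' patient (or parent) and one from the clinician.
#'
#' @param age Age in whole years; the engine accepts 6-65.
#' @param sex `"male"` or `"female"`.
#' @param adhd_subtype `"inattentive"`, `"hyperactive"` or `"combined"`.
#' @param symptom_severity Baseline severity score.
#' @param comorbidities,current_treatments,history_failures,history_serious_ae
#'   Character vectors of condition / drug codes.
#' @param psychotherapy Logical: receiving psychotherapy for ADHD.
#' @return `patient_profile` / `patient_case` objects.
#' @export
patient_profile <- function(age, sex, adhd_subtype = "combined",
                            symptom_severity = NA_real_,
                            comorbidities = character(0),
                            current_treatments = character(0),
                            history_failures = character(0),
                            history_serious_ae = character(0),
                            psychotherapy = FALSE) {
  sex <- match.arg(sex, c("male", "female"))
  adhd_subtype <- match.arg(adhd_subtype,
                            c("inattentive", "hyperactive", "combined"))
  if (age < 6 || age > 65)
    stop("patient age must be within 6-65 (engine validity range)")
  structure(list(age = as.numeric(age), sex = sex,
                 adhd_subtype = adhd_subtype,
                 symptom_severity = as.numeric(symptom_severity),
                 comorbidities = unique(as.character(comorbidities)),
                 current_treatments = unique(as.character(current_treatments)),
                 history_failures = unique(as.character(history_failures)),
                 history_serious_ae = unique(as.character(history_serious_ae)),
                 psychotherapy = isTRUE(psychotherapy)),
            class = "patient_profile")
}

#' @rdname patient_profile
#' @param case_id Unique case identifier.
#' @param profile A [patient_profile()].
#' @param ratings data.frame with columns `rater` (`"patient"`/`"clinician"`),
#'   `outcome_id`, `score` (integer 1-9).
#' @export
patient_case <- function(case_id, profile, ratings) {
  stopifnot(inherits(profile, "patient_profile"), is.data.frame(ratings))
  req <- c("rater", "outcome_id", "score")
  if (!all(req %in% names(ratings)))
    stop("ratings need columns rater, outcome_id, score")
  bad <- !is.na(ratings$score) &
    (ratings$score < 1 | ratings$score > 9 | ratings$score %% 1 != 0)
  if (any(bad))
    stop("case '", case_id, "': rating out of 1-9 for outcome ",
         paste(ratings$outcome_id[bad], collapse = ", "))
  if (anyDuplicated(ratings[, c("rater", "outcome_id")]))
    stop("case '", case_id, "': duplicate (rater, outcome) rating")
  ratings <- ratings[order(ratings$rater, ratings$outcome_id), req]
  rownames(ratings) <- NULL
  structure(list(case_id = case_id, profile = profile, ratings = ratings),
            class = "patient_case")
}

# ---- validation ------------------------------------------------------------

finding <- function(severity, record, message)
  data.frame(severity = severity, record = record, message = message)

#' Validate an evidence corpus
#'
#' Checks every structural invariant of the corpus (arm counts, event
#' bounds, cross-references into the outcome catalogue and drug registry)
#' and returns the findings as data rather than raising conditions: an empty
#' report means the corpus is valid.
#'
#' @param corpus An `evidence_corpus` (possibly structurally raw).
#' @return A data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `record` and `message`; zero rows when valid.
#' @examples
#' corp <- generate_corpus(sim_config(seed = 1))
#' nrow(validate_corpus(corp))   # 0
#' @export
validate_corpus <- function(corpus) {
  out <- list()
  add <- function(sev, rec, msg) out[[length(out) + 1]] <<- finding(sev, rec, msg)
  oids <- corpus$outcomes$outcome_id
  drugs <- corpus$drugs$drug
  ids <- vapply(corpus$trials, function(t) t$trial_id, character(1))
  if (anyDuplicated(ids))
    add("error", "corpus", paste("duplicate trial_id:",
                                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (tr in corpus$trials) {
    rec <- tr$trial_id
    roles <- vapply(tr$arms, function(a) a$arm_role, character(1))
    if (sum(roles == "placebo") != 1)
      add("error", rec, "trial must have exactly one placebo arm")
    if (!tr$drug %in% drugs)
      add("error", rec, paste0("unknown drug '", tr$drug, "'"))
    if (tr$eligibility$age_min > tr$eligibility$age_max)
      add("error", rec, "eligibility age_min > age_max")
    for (a in tr$arms) {
      if (a$arm_role == "intervention" && a$drug == "placebo")
        add("error", rec, "intervention arm labelled 'placebo'")
      if (a$n < 1) add("error", rec, "arm with n < 1")
      for (oid in names(a$continuous)) {
        if (!oid %in% oids)
          add("error", rec, paste0("unknown outcome reference '", oid, "'"))
        cs <- a$continuous[[oid]]
        if (!is.null(cs$sd) && (!is.finite(cs$sd) || cs$sd <= 0))
          add("error", rec, paste0("sd <= 0 for outcome '", oid, "'"))
      }
      for (oid in names(a$events)) {
        if (!oid %in% oids)
          add("error", rec, paste0("unknown outcome reference '", oid, "'"))
        ev <- a$events[[oid]]
        if (ev < 0 || ev > a$n)
          add("error", rec, paste0("events outside [0, n] for outcome '", oid, "'"))
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(severity = character(0), record = character(0),
               message = character(0))
}

# ---- JSON (de)serialization ------------------------------------------------

elig_to_list <- function(e) {
  list(age_min = e$age_min, age_max = e$age_max,
       sexes_allowed = I(e$sexes_allowed),
       required_diagnosis = e$required_diagnosis,
       excluded_comorbidities = I(e$excluded_comorbidities),
       excluded_cotreatments = I(e$excluded_cotreatments),
       min_severity = e$min_severity,
       other_flags = as.list(e$other_flags))
}

trial_to_list <- function(tr) {
  list(trial_id = tr$trial_id, drug = tr$drug,
       dose_mg_per_day = tr$dose_mg_per_day, drug_class = tr$drug_class,
       year = tr$year, risk_of_bias = tr$risk_of_bias,
       endpoint_scores = tr$endpoint_scores,
       eligibility = elig_to_list(tr$eligibility),
       arms = lapply(tr$arms, function(a)
         list(arm_role = a$arm_role, drug = a$drug,
              dose_mg_per_day = a$dose_mg_per_day, n = a$n,
              continuous = a$continuous, events = a$events)))
}

#' Read and write evidence corpora
#'
#' The corpus schema is this package's own JSON document: top-level keys
#' `outcomes` (the catalogue table), `drugs` (the registry table) and
#' `trials` (array of trial records).  Writing then reading is the identity
#' on every corpus the package can represent.
#'
#' The CSV bundle dialect is a directory of five UTF-8 comma-separated
#' tables with header rows and `.` decimals: `outcomes.csv`, `drugs.csv`,
#' `trials.csv` (one row per trial, eligibility columns with `;`-separated
#' set fields), `arms.csv` and `arm_outcomes.csv` (one row per arm and
#' outcome, `mean`/`sd` filled for continuous outcomes, `events` for
#' dichotomous ones).
#'
#' @param corpus An `evidence_corpus`.
#' @param path File path of the JSON document, or the bundle directory.
#' @param format `"json"` or `"csv-bundle"`.
#' @return `read_corpus()` returns a validated `evidence_corpus`;
#'   `write_corpus()` returns `path` invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("json", "csv-bundle")) {
  format <- match.arg(format)
  if (format == "csv-bundle") return(write_corpus_csv(corpus, path))
  doc <- list(schema = "metarec-corpus/1",
              outcomes = corpus$outcomes,
              drugs = corpus$drugs,
              trials = lapply(corpus$trials, trial_to_list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

semi_join_chr <- function(x) paste(x, collapse = ";")
semi_split_chr <- function(x)
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]

write_corpus_csv <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  w(as.data.frame(corpus$outcomes), "outcomes.csv")
  w(corpus$drugs, "drugs.csv")
  trials <- do.call(rbind, lapply(corpus$trials, function(tr) {
    e <- tr$eligibility
    data.frame(trial_id = tr$trial_id, drug = tr$drug,
               dose_mg_per_day = tr$dose_mg_per_day,
               drug_class = tr$drug_class, year = tr$year,
               risk_of_bias = tr$risk_of_bias,
               endpoint_scores = tr$endpoint_scores,
               age_min = e$age_min, age_max = e$age_max,
               sexes_allowed = semi_join_chr(e$sexes_allowed),
               required_diagnosis = e$required_diagnosis,
               excluded_comorbidities = semi_join_chr(e$excluded_comorbidities),
               excluded_cotreatments = semi_join_chr(e$excluded_cotreatments),
               min_severity = e$min_severity %||% NA_real_)
  }))
  w(trials, "trials.csv")
  arms <- list(); aouts <- list()
  for (tr in corpus$trials)
    for (ai in seq_along(tr$arms)) {
      a <- tr$arms[[ai]]
      arms[[length(arms) + 1]] <-
        data.frame(trial_id = tr$trial_id, arm_index = ai,
                   arm_role = a$arm_role, drug = a$drug,
                   dose_mg_per_day = a$dose_mg_per_day, n = a$n)
      for (oid in names(a$continuous))
        aouts[[length(aouts) + 1]] <-
          data.frame(trial_id = tr$trial_id, arm_index = ai,
                     outcome_id = oid, mean = a$continuous[[oid]]$mean,
                     sd = a$continuous[[oid]]$sd, events = NA_integer_)
      for (oid in names(a$events))
        aouts[[length(aouts) + 1]] <-
          data.frame(trial_id = tr$trial_id, arm_index = ai,
                     outcome_id = oid, mean = NA_real_, sd = NA_real_,
                     events = a$events[[oid]])
    }
  w(do.call(rbind, arms), "arms.csv")
  w(do.call(rbind, aouts), "arm_outcomes.csv")
  invisible(dir)
}

read_corpus_csv <- function(dir) {
  r <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("corpus bundle '", dir, "' is missing ", f)
    read.csv(p, stringsAsFactors = FALSE)
  }
  outcomes <- outcome_catalogue(r("outcomes.csv"))
  drugs <- r("drugs.csv")
  trials_df <- r("trials.csv"); arms_df <- r("arms.csv")
  ao_df <- r("arm_outcomes.csv")
  trials <- lapply(seq_len(nrow(trials_df)), function(i) {
    t <- trials_df[i, ]
    elig <- eligibility_criteria(
      t$age_min, t$age_max, semi_split_chr(t$sexes_allowed),
      t$required_diagnosis,
      semi_split_chr(t$excluded_comorbidities),
      semi_split_chr(t$excluded_cotreatments),
      if (is.na(t$min_severity)) NULL else t$min_severity)
    adf <- arms_df[arms_df$trial_id == t$trial_id, , drop = FALSE]
    arms <- lapply(seq_len(nrow(adf)), function(j) {
      a <- adf[j, ]
      od <- ao_df[ao_df$trial_id == t$trial_id &
                    ao_df$arm_index == a$arm_index, , drop = FALSE]
      cont <- list(); ev <- list()
      for (k in seq_len(nrow(od))) {
        o <- od[k, ]
        if (!is.na(o$events)) ev[[o$outcome_id]] <- as.integer(o$events)
        else cont[[o$outcome_id]] <- list(mean = o$mean, sd = o$sd)
      }
      arm_summary(a$arm_role, a$drug, a$n, a$dose_mg_per_day,
                  continuous = cont, events = ev)
    })
    trial_record(t$trial_id, t$drug, t$drug_class, elig, arms,
                 t$risk_of_bias, t$year, t$dose_mg_per_day,
                 t$endpoint_scores)
  })
  corp <- structure(list(outcomes = outcomes, trials = trials,
                         drugs = drugs), class = "evidence_corpus")
  rep <- validate_corpus(corp)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs))
    stop("'", dir, "': invalid corpus:\n",
         paste0("  - [", errs$record, "] ", errs$message, collapse = "\n"))
  corp
}

chr0 <- function(x) if (is.null(x)) character(0) else as.character(unlist(x))

list_to_trial <- function(tl, path) {
  el <- tl$eligibility
  elig <- eligibility_criteria(
    age_min = el$age_min, age_max = el$age_max,
    sexes_allowed = chr0(el$sexes_allowed),
    required_diagnosis = el$required_diagnosis %||% "adhd",
    excluded_comorbidities = chr0(el$excluded_comorbidities),
    excluded_cotreatments = chr0(el$excluded_cotreatments),
    min_severity = el$min_severity,
    other_flags = unlist(el$other_flags) %||% logical(0))
  arms <- lapply(tl$arms, function(a) {
    cont <- lapply(a$continuous, function(cs) list(mean = cs$mean, sd = cs$sd))
    ev <- lapply(a$events, as.integer)
    arm_summary(arm_role = a$arm_role, drug = a$drug,
                n = a$n, dose_mg_per_day = a$dose_mg_per_day %||% NA_real_,
                continuous = cont, events = ev)
  })
  trial_record(trial_id = tl$trial_id, drug = tl$drug,
               drug_class = tl$drug_class, eligibility = elig, arms = arms,
               risk_of_bias = tl$risk_of_bias, year = tl$year,
               dose_mg_per_day = tl$dose_mg_per_day %||% NA_real_,
               endpoint_scores = isTRUE(tl$endpoint_scores))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_corpus
#' @export
read_corpus <- function(path, format = c("json", "csv-bundle")) {
  format <- match.arg(format)
  if (format == "csv-bundle") return(read_corpus_csv(path))
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path)
  if (is.null(doc$trials)) stop("'", path, "': not a corpus document")
  outcomes <- outcome_catalogue(
    do.call(rbind, lapply(doc$outcomes, as.data.frame)))
  drugs <- do.call(rbind, lapply(doc$drugs, as.data.frame))
  trials <- lapply(doc$trials, function(tl)
    tryCatch(list_to_trial(tl, path), error = function(e)
      stop("'", path, "', trial '", tl$trial_id %||% "?", "': ",
           conditionMessage(e), call. = FALSE)))
  corp <- structure(list(outcomes = outcomes, trials = trials, drugs = drugs),
                    class = "evidence_corpus")
  rep <- validate_corpus(corp)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs))
    stop("'", path, "': invalid corpus:\n",
         paste0("  - [", errs$record, "] ", errs$message, collapse = "\n"))
  corp
}

#' Read and write patient cohorts
#'
#' Cohorts are stored as a JSON array of cases, each with a `profile` object
#' and a `ratings` array of `(rater, outcome_id, score)` triples.  Every
#' case must carry ratings from both the patient and the clinician; scores
#' outside 1-9 are rejected with the case and outcome named.
#'
#' @param cases List of [patient_case()] objects.
#' @param path File path.
#' @param catalogue Outcome catalogue used to flag missing ratings.
#' @return `read_patient_records()` returns a list of `patient_case`;
#'   missing ratings are reported via warning.
#' @export
write_patient_records <- function(cases, path) {
  doc <- lapply(cases, function(cs)
    list(case_id = cs$case_id,
         profile = list(
           age = cs$profile$age, sex = cs$profile$sex,
           adhd_subtype = cs$profile$adhd_subtype,
           symptom_severity = cs$profile$symptom_severity,
           comorbidities = I(cs$profile$comorbidities),
           current_treatments = I(cs$profile$current_treatments),
           history_failures = I(cs$profile$history_failures),
           history_serious_ae = I(cs$profile$history_serious_ae),
           psychotherapy = cs$profile$psychotherapy),
         ratings = cs$ratings))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_patient_records
#' @export
read_patient_records <- function(path, catalogue = default_outcome_catalogue()) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path)
  cases <- lapply(doc, function(cl) {
    pr <- cl$profile
    prof <- patient_profile(
      age = pr$age, sex = pr$sex, adhd_subtype = pr$adhd_subtype,
      symptom_severity = pr$symptom_severity %||% NA_real_,
      comorbidities = chr0(pr$comorbidities),
      current_treatments = chr0(pr$current_treatments),
      history_failures = chr0(pr$history_failures),
      history_serious_ae = chr0(pr$history_serious_ae),
      psychotherapy = isTRUE(pr$psychotherapy))
    ratings <- do.call(rbind, lapply(cl$ratings, function(r) {
      if (is.null(r$score) || r$score < 1 || r$score > 9)
        stop("case '", cl$case_id, "': rating outside 1-9 for outcome '",
             r$outcome_id, "'", call. = FALSE)
      data.frame(rater = r$rater, outcome_id = r$outcome_id,
                 score = as.integer(r$score))
    }))
    patient_case(cl$case_id, prof, ratings)
  })
  for (cs in cases)
    for (rt in c("patient", "clinician")) {
      have <- cs$ratings$outcome_id[cs$ratings$rater == rt]
      miss <- setdiff(catalogue$outcome_id, have)
      if (length(miss))
        warning("case '", cs$case_id, "': missing ", rt, " ratings for ",
                paste(miss, collapse = ", "), call. = FALSE)
    }
  cases
}
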