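# shared tiny fixtures, built in code at test time

`%||%` <- function(a, b) if (is.null(a)) b else a

# a two-arm trial with an ADHD-symptom change score, a seizure count and a
# discontinuation count per arm
mini_trial <- function(trial_id, drug, class = "stimulant-MPH",
                       dose = NA_real_,
                       mean_i = -10, mean_p = -4, sd = 10, n = 100,
                       seiz_i = 2L, seiz_p = 2L,
                       disc_i = 10L, disc_p = 10L,
                       rob = "low",
                       age_min = 6, age_max = 17,
                       excluded_comorbidities = character(0),
                       excluded_cotreatments = character(0),
                       min_severity = NULL) {
  trial_record(
    trial_id, drug, class, dose_mg_per_day = dose,
    eligibility = eligibility_criteria(
      age_min, age_max,
      excluded_comorbidities = excluded_comorbidities,
      excluded_cotreatments = excluded_cotreatments,
      min_severity = min_severity),
    arms = list(
      arm_summary("intervention", drug, n, dose,
                  continuous = list(adhd_symptoms = list(mean = mean_i, sd = sd)),
                  events = list(seizures = seiz_i,
                                treatment_discontinuation = disc_i)),
      arm_summary("placebo", "placebo", n,
                  continuous = list(adhd_symptoms = list(mean = mean_p, sd = sd)),
                  events = list(seizures = seiz_p,
                                treatment_discontinuation = disc_p))),
    risk_of_bias = rob)
}

# 6 trials over 3 drugs (the bundled fixture corpus shape)
mini_corpus <- function() {
  evidence_corpus(list(
    mini_trial("mph-20", "methylphenidate", dose = 20),
    mini_trial("mph-40", "methylphenidate", dose = 40,
               excluded_comorbidities = "epilepsy"),
    mini_trial("ldx-1", "lisdexamfetamine", class = "stimulant-AMP", dose = 50),
    mini_trial("ldx-2", "lisdexamfetamine", class = "stimulant-AMP", dose = 70),
    mini_trial("atx-1", "atomoxetine", class = "nonstimulant-NRI", dose = 60),
    mini_trial("atx-2", "atomoxetine", class = "nonstimulant-NRI", dose = 60,
               age_min = 18, age_max = 65)
  ))
}

full_ratings <- function(score_patient = 5L, score_clinician = 5L,
                         catalogue = default_outcome_catalogue()) {
  rbind(
    data.frame(rater = "patient", outcome_id = catalogue$outcome_id,
               score = score_patient),
    data.frame(rater = "clinician", outcome_id = catalogue$outcome_id,
               score = score_clinician))
}

mini_case <- function(case_id = "C1", age = 12, sex = "male",
                      critical_patient = "adhd_symptoms",
                      critical_clinician = "adhd_symptoms", ...) {
  r <- full_ratings()
  r$score[r$rater == "patient" &
            r$outcome_id %in% critical_patient] <- 9L
  r$score[r$rater == "clinician" &
            r$outcome_id %in% critical_clinician] <- 9L
  patient_case(case_id, patient_profile(age, sex, ...), r)
}

# verdict stub for rule-level tests (no meta-analysis behind it)
stub_verdict <- function(outcome_id, kind, verdict, quality = "low") {
  structure(list(outcome_id = outcome_id, kind = kind, verdict = verdict,
                 quality = quality, result = NULL),
            class = "outcome_verdict")
}
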