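#' Outcome verdicts
#'
#' Classifies a pooled, oriented effect into `improves` / `worsens` /
#' `inconclusive`: because every effect is oriented so that negative favors
#' the intervention, the verdict is `improves` when the 95% CI lies entirely
#' below zero, `worsens` when entirely above, and `inconclusive` otherwise.
#'
#' @param result A `meta_result` from [meta_analyse_group()].
#' @param outcome The matching catalogue row.
#' @return An `outcome_verdict`: `outcome_id`, `kind`, `verdict`, `quality`
#'   and the source `result`.
#' @export
classify_outcome_effect <- function(result, outcome) {
  p <- result$pooled
  verdict <- if (p$ci_high < 0) "improves"
             else if (p$ci_low > 0) "worsens"
             else "inconclusive"
  structure(list(outcome_id = outcome$outcome_id, kind = outcome$kind,
                 verdict = verdict, quality = result$quality,
                 result = result),
            class = "outcome_verdict")
}

#' Risk-benefit judgment
#'
#' The engine's central decision rule.  An intervention is *favorable* when
#' it improves a strict majority of the critical efficacy outcomes with
#' available evidence and does not worsen any critical safety outcome or
#' treatment discontinuation; *unfavorable* when it fails that majority and
#' worsens at least one safety/discontinuation outcome; *neutral* in every
#' other case.  An exact half is not a majority.  With no critical efficacy
#' evidence at all the judgment is neutral with an `insufficient-evidence`
#' flag.  The judgment quality is the minimum outcome-level evidence quality
#' among the contributing verdicts, mapped onto three rungs
#' (`high`/`moderate` kept, `low` and `very_low` collapse to `low`).
#'
#' @param verdicts List of [classify_outcome_effect()] verdicts covering the
#'   critical outcomes with available evidence (plus discontinuation).
#' @param group Group key label.
#' @return A `risk_benefit_judgment`: `judgment`, `judgment_quality`,
#'   `flags`, counts, and the contributing `verdicts`.
#' @export
judge_risk_benefit <- function(verdicts, group = NA_character_) {
  kinds <- vapply(verdicts, `[[`, character(1), "kind")
  vs <- vapply(verdicts, `[[`, character(1), "verdict")
  eff <- vs[kinds == "efficacy"]
  harm <- vs[kinds %in% c("safety", "discontinuation")]
  flags <- character(0)
  n_eff <- length(eff)
  improved <- sum(eff == "improves")
  any_harm <- any(harm == "worsens")
  if (n_eff == 0) {
    judgment <- "neutral"
    flags <- c(flags, "insufficient-evidence")
  } else if (improved > n_eff / 2 && !any_harm) {
    judgment <- "favorable"
  } else if (!(improved > n_eff / 2) && any_harm) {
    judgment <- "unfavorable"
  } else {
    judgment <- "neutral"
  }
  quals <- vapply(verdicts, `[[`, character(1), "quality")
  jq <- if (!length(quals)) "low" else {
    mq <- quality_levels[min(match(quals, quality_levels))]
    c(very_low = "low", low = "low", moderate = "moderate",
      high = "high")[[mq]]
  }
  structure(list(group = group, judgment = judgment, judgment_quality = jq,
                 n_efficacy = n_eff, n_improved = improved,
                 any_harm_worsens = any_harm, flags = flags,
                 verdicts = verdicts),
            class = "risk_benefit_judgment")
}

#' Derive a directed, strength-rated recommendation
#'
#' Favorable judgments recommend *for* the intervention, unfavorable
#' *against*, neutral yields no recommendation.  The recommendation is
#' *strong* when the judgment quality is high or moderate and *weak* when it
#' is low; without a direction the strength is not applicable.
#'
#' @param judgment A [judge_risk_benefit()] result.
#' @return A `recommendation`: `group`, `direction` (`for`/`against`/
#'   `none`), `strength` (`strong`/`weak`/`not_applicable`), `label` and the
#'   source `judgment`.
#' @export
derive_recommendation <- function(judgment) {
  direction <- switch(judgment$judgment, favorable = "for",
                      unfavorable = "against", neutral = "none")
  strength <- if (direction == "none") "not_applicable"
              else if (judgment$judgment_quality %in% c("high", "moderate"))
                "strong" else "weak"
  label <- switch(direction,
                  "for" = paste0(strength, "ly in favor"),
                  "against" = paste0(strength, "ly against"),
                  "none" = "no recommendation")
  structure(list(group = judgment$group, direction = direction,
                 strength = strength, label = label, judgment = judgment),
            class = "recommendation")
}

#' Run the full engine for one patient
#'
#' Pipeline: threshold both raters' preference ratings, combine them under
#' the chosen mode, assemble the PICO question at the chosen pooling level,
#' meta-analyse every eligible intervention group for every critical outcome
#' (treatment discontinuation is always evaluated when data exist), grade
#' evidence quality, apply the risk-benefit rule and derive one
#' recommendation per group.
#'
#' @param case A [patient_case()].
#' @param corpus An `evidence_corpus`.
#' @param mode `"comprehensive"` or `"conjoint"`.
#' @param level Pooling level (string or [pooling_level()]).
#' @param config A [grade_config()].
#' @param threshold Criticality threshold (default 7).
#' @return An `engine_result`: `status` (`"ok"`, `"no-critical-preferences"`
#'   or `"no-eligible-trials"`), `critical_set`, per-group `results`
#'   (meta-analyses keyed `group:outcome`), `judgments`, `recommendations`
#'   (data.frame) and `favorable_set` (drug/group keys recommended for).
#' @examples
#' fx <- end_to_end_fixture("favorable_drug")
#' res <- run_engine(fx$cohort[[1]], fx$corpus)
#' res$recommendations
#' @export
run_engine <- function(case, corpus, mode = "comprehensive",
                       level = pooling_level("L3"),
                       config = grade_config(), threshold = 7) {
  crit <- suppressWarnings(mark_critical(case$ratings, threshold))
  combined <- combine_preferences(crit$patient %||% character(0),
                                  crit$clinician %||% character(0), mode)
  pico <- build_pico(case$profile, combined, corpus, level)
  base <- list(case_id = case$case_id, mode = mode, pico = pico,
               critical_set = combined, status = pico$status,
               results = list(), judgments = list(),
               recommendations = data.frame(group = character(0),
                                            direction = character(0),
                                            strength = character(0),
                                            quality = character(0)),
               favorable_set = character(0))
  if (pico$status != "ok") return(structure(base, class = "engine_result"))

  cat_rows <- split(corpus$outcomes, corpus$outcomes$outcome_id)
  disc_ids <- corpus$outcomes$outcome_id[
    corpus$outcomes$kind == "discontinuation"]
  analysis_ids <- union(combined, disc_ids)

  results <- list(); judgments <- list(); recs <- list()
  for (g in names(pico$groups)) {
    verdicts <- list()
    for (oid in analysis_ids) {
      oc <- cat_rows[[oid]]
      if (is.null(oc)) next
      res <- meta_analyse_group(pico$groups[[g]], oc, group = g,
                                config = config)
      if (is.null(res)) next
      results[[paste(g, oid, sep = ":")]] <- res
      # only critical outcomes (plus discontinuation) feed the judgment
      if (oid %in% combined || oid %in% disc_ids)
        verdicts[[oid]] <- classify_outcome_effect(res, oc)
    }
    jd <- judge_risk_benefit(verdicts, group = g)
    judgments[[g]] <- jd
    rec <- derive_recommendation(jd)
    recs[[g]] <- data.frame(group = g, direction = rec$direction,
                            strength = rec$strength,
                            quality = jd$judgment_quality)
  }
  recommendations <- do.call(rbind, recs)
  rownames(recommendations) <- NULL
  base$results <- results
  base$judgments <- judgments
  base$recommendations <- recommendations
  base$favorable_set <-
    sort(recommendations$group[recommendations$direction == "for"])
  structure(base, class = "engine_result")
}

fmt_num <- function(x) formatC(x, format = "f", digits = 3)

#' Render the therapeutic report
#'
#' One section per intervention group and analysed outcome: pooled effect
#' with CI, number of studies, evidence quality with downgrade reasons, and
#' the verdict; followed by the recommendation list sorted by direction
#' (for, against, none) then strength.  Rendering is deterministic, so a
#' report regenerated from the same engine result is byte-identical.
#'
#' @param engine_result A [run_engine()] result.
#' @return A single markdown string.
#' @export
render_report <- function(engine_result) {
  ln <- c(sprintf("# Therapeutic report — case %s", engine_result$case_id),
          "",
          sprintf("Mode: %s; pooling level: %s; critical outcomes: %s",
                  engine_result$mode, engine_result$pico$level$level,
                  if (length(engine_result$critical_set))
                    paste(engine_result$critical_set, collapse = ", ")
                  else "(none)"),
          "")
  if (engine_result$status != "ok") {
    ln <- c(ln, switch(engine_result$status,
      "no-critical-preferences" =
        "No critical preferences were selected; no recommendation can be made.",
      "no-eligible-trials" =
        "No trials match this patient's characteristics; no recommendation can be made."))
    return(paste(ln, collapse = "\n"))
  }
  for (key in sort(names(engine_result$results))) {
    res <- engine_result$results[[key]]
    p <- res$pooled
    reasons <- if (length(res$downgrade_reasons))
      paste0(" (-", unlist(res$downgrade_reasons), " ",
             names(res$downgrade_reasons), collapse = ",")
    else " (no downgrades"
    verdict <- if (p$ci_high < 0) "improves"
               else if (p$ci_low > 0) "worsens" else "inconclusive"
    ln <- c(ln,
            sprintf("## %s — %s", res$group, res$outcome_id),
            sprintf("%s %s [95%% CI %s, %s], k = %d, n = %d",
                    p$measure, fmt_num(p$value), fmt_num(p$ci_low),
                    fmt_num(p$ci_high), res$k, p$n_total),
            sprintf("Quality: %s%s); verdict: %s", res$quality,
                    reasons, verdict),
            "")
  }
  recs <- engine_result$recommendations
  ord <- order(match(recs$direction, c("for", "against", "none")),
               match(recs$strength, c("strong", "weak", "not_applicable")),
               recs$group)
  recs <- recs[ord, ]
  ln <- c(ln, "## Recommendations", "")
  for (i in seq_len(nrow(recs)))
    ln <- c(ln, sprintf("- %s: %s (%s, quality %s)", recs$group[i],
                        recs$direction[i], recs$strength[i], recs$quality[i]))
  paste(ln, collapse = "\n")
}

#' Cohort-level recommender output
#'
#' Runs the engine over a cohort and collects, per patient, the set of
#' interventions recommended *for* — the shape consumed by the
#' recommender-comparison statistics ([overlap_concordance()],
#' [distinct_recommendation_sets()], [system_distance_matrix()]).
#'
#' @inheritParams run_engine
#' @param cases List of [patient_case()] objects.
#' @param system_id Label for the comparison toolkit (default `"engine"`).
#' @return A `system_output`: `system_id` plus `sets`, a named list of
#'   per-case character vectors of drug codes.
#' @export
engine_output <- function(cases, corpus, mode = "comprehensive",
                          level = pooling_level("L3"),
                          config = grade_config(), threshold = 7,
                          system_id = "engine") {
  sets <- lapply(cases, function(cs)
    run_engine(cs, corpus, mode, level, config, threshold)$favorable_set)
  names(sets) <- vapply(cases, `[[`, character(1), "case_id")
  system_output(system_id, sets)
}

#' @rdname engine_output
#' @param sets Named list of per-case drug-code vectors.
#' @export
system_output <- function(system_id, sets) {
  structure(list(system_id = system_id,
                 sets = lapply(sets, function(s) sort(unique(s)))),
            class = "system_output")
}
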