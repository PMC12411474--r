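test_that("outcome verdicts follow the oriented CI rule", {
  res <- function(value, se) {
    r <- pool_effects(list(effect_estimate("SMD", value, se, 400, "t", "low")),
                      "fixed")
    grade_quality(r)
  }
  sym <- default_outcome_catalogue()[1, ]  # decrease-is-good efficacy
  expect_equal(classify_outcome_effect(res(-0.6, 0.15), sym)$verdict,
               "improves")                       # CI (-0.9, -0.3)
  expect_equal(classify_outcome_effect(res(0.59, 0.2), sym)$verdict,
               "worsens")                        # CI above 0 (OR 1.8-like)
  expect_equal(classify_outcome_effect(res(0.1, 0.2), sym)$verdict,
               "inconclusive")                   # CI spans 0
})

# independent truth-table oracle, coded from the rule text:
# favorable  = improves a strict majority of critical efficacy outcomes AND
#              worsens no critical safety outcome nor discontinuation
# unfavorable = fails that majority AND worsens >= 1 safety/discontinuation
# neutral otherwise; no efficacy evidence at all is neutral
rule_oracle <- function(eff, harm) {
  if (length(eff) == 0) return("neutral")
  majority_improved <- sum(eff == "improves") * 2 > length(eff)
  harm_worsened <- "worsens" %in% harm
  if (majority_improved && !harm_worsened) return("favorable")
  if (!majority_improved && harm_worsened) return("unfavorable")
  "neutral"
}

test_that("risk-benefit judgment matches the paper-rule examples", {
  v <- function(eff, harm) c(
    lapply(seq_along(eff), function(i)
      stub_verdict(paste0("e", i), "efficacy", eff[i])),
    lapply(seq_along(harm), function(i)
      stub_verdict(paste0("s", i), "safety", harm[i])))

  # 2 of 3 efficacy improve, no harms worsen -> favorable
  j <- judge_risk_benefit(v(c("improves", "improves", "inconclusive"),
                            c("inconclusive")))
  expect_equal(j$judgment, "favorable")
  # 1 of 3 improve, 1 safety worsens -> unfavorable
  expect_equal(judge_risk_benefit(
    v(c("improves", "inconclusive", "inconclusive"), c("worsens")))$judgment,
    "unfavorable")
  # 2 of 3 improve but a safety worsens -> neutral (all other cases)
  expect_equal(judge_risk_benefit(
    v(c("improves", "improves", "inconclusive"), c("worsens")))$judgment,
    "neutral")
  # an exact half is not a majority
  expect_equal(judge_risk_benefit(
    v(c("improves", "inconclusive"), character(0)))$judgment, "neutral")
  # no efficacy evidence: neutral with a flag
  j0 <- judge_risk_benefit(v(character(0), c("worsens")))
  expect_equal(j0$judgment, "neutral")
  expect_true("insufficient-evidence" %in% j0$flags)
})

test_that("judgment agrees with the exhaustive truth-table oracle", {
  verdict_levels <- c("improves", "worsens", "inconclusive")
  for (ne in 0:4) for (ns in 0:4) {
    if (ne == 0 && ns == 0) next
    grid <- as.matrix(expand.grid(rep(list(verdict_levels), ne + ns),
                                  stringsAsFactors = FALSE))
    got <- character(nrow(grid)); want <- character(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      eff <- grid[r, seq_len(ne)]
      harm <- grid[r, ne + seq_len(ns)]
      vs <- c(
        lapply(seq_along(eff), function(i)
          stub_verdict(paste0("e", i), "efficacy", eff[[i]])),
        lapply(seq_along(harm), function(i)
          stub_verdict(paste0("s", i),
                       if (i == 1) "discontinuation" else "safety",
                       harm[[i]])))
      got[r] <- judge_risk_benefit(vs)$judgment
      want[r] <- rule_oracle(eff, harm)
    }
    expect_identical(got, want, label = paste0("grid ne=", ne, " ns=", ns))
  }
})

test_that("adding an inconclusive verdict never flips the direction", {
  set.seed(3)
  verdict_levels <- c("improves", "worsens", "inconclusive")
  for (i in 1:60) {
    eff <- sample(verdict_levels, sample(1:4, 1), replace = TRUE)
    harm <- sample(verdict_levels, sample(0:3, 1), replace = TRUE)
    mk <- function(eff, harm) judge_risk_benefit(c(
      lapply(seq_along(eff), function(i)
        stub_verdict(paste0("e", i), "efficacy", eff[i])),
      lapply(seq_along(harm), function(i)
        stub_verdict(paste0("s", i), "safety", harm[i]))))
    before <- mk(eff, harm)$judgment
    after <- mk(c(eff, "inconclusive"), harm)$judgment
    expect_false(before == "favorable" && after == "unfavorable")
    expect_false(before == "unfavorable" && after == "favorable")
  }
})

test_that("judgment quality maps the minimum outcome quality onto 3 rungs", {
  v <- function(q1, q2) list(
    stub_verdict("e1", "efficacy", "improves", q1),
    stub_verdict("s1", "safety", "inconclusive", q2))
  expect_equal(judge_risk_benefit(v("high", "high"))$judgment_quality, "high")
  expect_equal(judge_risk_benefit(v("high", "moderate"))$judgment_quality,
               "moderate")
  expect_equal(judge_risk_benefit(v("moderate", "low"))$judgment_quality,
               "low")
  expect_equal(judge_risk_benefit(v("high", "very_low"))$judgment_quality,
               "low")
})

test_that("recommendations map judgment x quality to direction x strength", {
  jd <- function(judgment, q) structure(
    list(group = "g", judgment = judgment, judgment_quality = q,
         n_efficacy = 2L, n_improved = 2L, any_harm_worsens = FALSE,
         flags = character(0), verdicts = list()),
    class = "risk_benefit_judgment")
  r <- derive_recommendation(jd("favorable", "low"))
  expect_equal(c(r$direction, r$strength), c("for", "weak"))
  expect_equal(r$label, "weakly in favor")
  r2 <- derive_recommendation(jd("favorable", "moderate"))
  expect_equal(c(r2$direction, r2$strength), c("for", "strong"))
  r3 <- derive_recommendation(jd("unfavorable", "high"))
  expect_equal(c(r3$direction, r3$strength), c("against", "strong"))
  r4 <- derive_recommendation(jd("neutral", "high"))
  expect_equal(c(r4$direction, r4$strength), c("none", "not_applicable"))
})

test_that("the engine runs end to end and reports are deterministic", {
  corp <- mini_corpus()
  cs <- mini_case(critical_patient = c("adhd_symptoms", "seizures"),
                  critical_clinician = "adhd_symptoms")
  res <- run_engine(cs, corp, mode = "comprehensive", level = "L3")
  expect_equal(res$status, "ok")
  expect_setequal(res$recommendations$group,
                  c("methylphenidate", "lisdexamfetamine", "atomoxetine"))
  # one section per intervention x analysed outcome with evidence
  # (2 critical + always-checked discontinuation, all measured here)
  expect_equal(length(res$results), 3 * 3)
  rpt <- render_report(res)
  expect_identical(rpt, render_report(res))
  expect_match(rpt, "## Recommendations")

  # no-critical-preference and no-trial paths render a clear statement
  cs2 <- mini_case(critical_patient = "seizures",
                   critical_clinician = "quality_of_life")
  res2 <- run_engine(cs2, corp, mode = "conjoint")
  expect_equal(res2$status, "no-critical-preferences")
  expect_match(render_report(res2), "[Nn]o critical preferences")

  cs3 <- mini_case()
  corp_adult <- evidence_corpus(list(
    mini_trial("ad-1", "atomoxetine", class = "nonstimulant-NRI",
               age_min = 18, age_max = 65)))
  res3 <- run_engine(cs3, corp_adult)
  expect_equal(res3$status, "no-eligible-trials")
  expect_match(render_report(res3), "[Nn]o trials match")
})

test_that("engine_output collects per-patient favorable sets", {
  fx <- end_to_end_fixture("favorable_drug")
  out <- engine_output(fx$cohort[1:4], fx$corpus)
  expect_s3_class(out, "system_output")
  expect_length(out$sets, 4)
  expect_true(all(vapply(out$sets, function(s)
    fx$beneficial %in% s, logical(1))))
})
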