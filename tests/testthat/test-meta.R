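cat18 <- default_outcome_catalogue()
row_of <- function(oid) cat18[cat18$outcome_id == oid, ]

test_that("dichotomous arm effect matches direct 2x2 arithmetic", {
  tr <- mini_trial("t", "methylphenidate", seiz_i = 10L, seiz_p = 5L, n = 100)
  eff <- arm_effect(tr, row_of("seizures"))
  # independent oracle: OR = (10*95)/(90*5)
  expect_equal(eff$value, log((10 * 95) / (90 * 5)), tolerance = 1e-12)
  expect_equal(exp(eff$value), 2.1111, tolerance = 1e-4)
  expect_equal(eff$se, sqrt(1/10 + 1/90 + 1/5 + 1/95), tolerance = 1e-12)
  expect_equal(eff$n_total, 200L)
})

test_that("zero cells get the 0.5 continuity correction", {
  tr <- mini_trial("t", "methylphenidate", seiz_i = 0L, seiz_p = 5L, n = 100)
  eff <- arm_effect(tr, row_of("seizures"))
  # recomputed by hand with +0.5 on all four cells
  a <- 0.5; b <- 100.5; c_ <- 5.5; d <- 95.5
  expect_equal(eff$value, log((a * d) / (b * c_)), tolerance = 1e-12)
  expect_equal(eff$se, sqrt(1/a + 1/b + 1/c_ + 1/d), tolerance = 1e-12)
  expect_true(is.finite(eff$se))
})

test_that("continuous arm effect is a Hedges-corrected SMD", {
  # identical arms: SMD 0, CI spans 0
  tr0 <- mini_trial("t", "methylphenidate", mean_i = -4, mean_p = -4)
  e0 <- arm_effect(tr0, row_of("adhd_symptoms"))
  expect_equal(e0$value, 0)
  expect_true(e0$ci_low < 0 && e0$ci_high > 0)

  # hand-computed Hedges g for unequal arms
  tr <- mini_trial("t", "methylphenidate", mean_i = -10, mean_p = -4,
                   sd = 10, n = 100)
  e <- arm_effect(tr, row_of("adhd_symptoms"))
  J <- 1 - 3 / (4 * 198 - 1)
  expect_equal(e$value, J * (-6 / 10), tolerance = 1e-12)
  expect_equal(e$se, sqrt(200 / (100 * 100) + e$value^2 / 400),
               tolerance = 1e-12)

  # increase-is-good outcomes are sign-flipped so negative favors drug
  tr2 <- mini_trial("t2", "methylphenidate")
  tr2$arms[[1]]$continuous$quality_of_life <- list(mean = 5, sd = 8)
  tr2$arms[[2]]$continuous$quality_of_life <- list(mean = 1, sd = 8)
  e2 <- arm_effect(tr2, row_of("quality_of_life"))
  expect_lt(e2$value, 0)

  # outcome absent from an arm yields a typed marker
  mk <- arm_effect(tr0, row_of("insomnia"))
  expect_s3_class(mk, "outcome_not_measured")
})

test_that("two-study pooling matches the closed-form oracle", {
  e1 <- effect_estimate("SMD", 0.5, 0.2, 100, "a", "low")
  e2 <- effect_estimate("SMD", 0.1, 0.2, 100, "b", "low")

  fx <- pool_effects(list(e1, e2), "fixed")
  expect_equal(fx$pooled$value, 0.3, tolerance = 1e-12)
  expect_equal(fx$pooled$se, sqrt(1 / 50), tolerance = 1e-12)  # 0.1414
  expect_equal(fx$Q, 2.0, tolerance = 1e-12)
  expect_equal(fx$tau2, 0.04, tolerance = 1e-12)
  expect_equal(fx$I2, 50, tolerance = 1e-12)

  rx <- pool_effects(list(e1, e2), "random")
  expect_equal(rx$pooled$value, 0.3, tolerance = 1e-12)
  expect_equal(rx$pooled$se, 0.2, tolerance = 1e-12)
})

test_that("pooling limit cases behave by convention", {
  e1 <- effect_estimate("SMD", 0.5, 0.2, 100, "a", "low")
  # k = 1: pooled equals the single effect, tau2 = 0
  p1 <- pool_effects(list(e1), "random")
  expect_equal(p1$pooled$value, e1$value)
  expect_equal(p1$pooled$se, e1$se)
  expect_equal(p1$tau2, 0)
  expect_equal(p1$I2, 0)

  # identical effects: Q = 0, fixed = random
  twin <- pool_effects(list(e1, e1), "random")
  expect_equal(twin$Q, 0)
  expect_equal(twin$tau2, 0)
  expect_equal(twin$pooled$value,
               pool_effects(list(e1, e1), "fixed")$pooled$value)

  # Q < df truncates I2 and tau2 at zero
  e3 <- effect_estimate("SMD", 0.52, 0.4, 100, "c", "low")
  near <- pool_effects(list(e1, e3), "random")
  expect_equal(near$tau2, 0)
  expect_equal(near$I2, 0)

  # mixed measures refuse to pool
  lo <- effect_estimate("logOR", 0.3, 0.2, 100, "d", "low")
  expect_error(pool_effects(list(e1, lo)), "mixed")
})

test_that("pooling invariants hold on random inputs", {
  set.seed(7)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    effs <- lapply(seq_len(k), function(j)
      effect_estimate("SMD", rnorm(1, 0, 0.5), runif(1, 0.05, 0.4), 100,
                      paste0("t", j), "low"))
    y <- vapply(effs, `[[`, numeric(1), "value")
    fx <- pool_effects(effs, "fixed")
    rx <- pool_effects(effs, "random")
    expect_gte(fx$pooled$value, min(y))
    expect_lte(fx$pooled$value, max(y))
    # random CI never narrower than fixed
    expect_gte(rx$pooled$se, fx$pooled$se - 1e-12)
    # order invariance
    perm <- pool_effects(effs[sample(k)], "random")
    expect_equal(perm$pooled$value, rx$pooled$value, tolerance = 1e-9)
    expect_equal(perm$tau2, rx$tau2, tolerance = 1e-9)
    # duplicating the study set keeps the fixed point estimate,
    # cannot increase its se
    dup <- pool_effects(c(effs, effs), "fixed")
    expect_equal(dup$pooled$value, fx$pooled$value, tolerance = 1e-9)
    expect_lte(dup$pooled$se, fx$pooled$se + 1e-12)
  }
})

test_that("quality grading fires the documented triggers", {
  mk_res <- function(value = -0.8, se = 0.05, n = 900, rob = "low",
                     I2 = 0, k = 3) {
    effs <- lapply(seq_len(k), function(j)
      effect_estimate("SMD", value, se * sqrt(k), ceiling(n / k),
                      paste0("t", j), rob))
    r <- pool_effects(effs, "fixed")
    r$I2 <- I2
    r$pooled <- effect_estimate("SMD", value, se, n)
    r
  }
  # no trigger: high
  expect_equal(grade_quality(mk_res())$quality, "high")
  # dominant high-RoB weight
  g <- grade_quality(mk_res(rob = "high"))
  expect_equal(g$quality, "moderate")
  expect_named(g$downgrade_reasons, "risk_of_bias")
  # heterogeneity: one point above 50, two above 75
  expect_equal(grade_quality(mk_res(I2 = 60))$quality, "moderate")
  g2 <- grade_quality(mk_res(I2 = 80))
  expect_equal(g2$quality, "low")
  expect_equal(g2$downgrade_reasons$heterogeneity, 2L)
  # imprecision: small sample, or CI crossing null and threshold
  g3 <- grade_quality(mk_res(n = 120))
  expect_named(g3$downgrade_reasons, "imprecision")
  g4 <- grade_quality(mk_res(value = 0, se = 0.4, n = 900))
  expect_named(g4$downgrade_reasons, "imprecision")
  # all three triggers floor at very_low
  g5 <- grade_quality(mk_res(value = 0, se = 0.4, n = 120,
                             rob = "high", I2 = 90))
  expect_equal(g5$quality, "very_low")

  # monotonicity: worsening any single trigger never raises quality
  lv <- function(q) match(q, c("very_low", "low", "moderate", "high"))
  base_cases <- list(mk_res(), mk_res(I2 = 60), mk_res(rob = "high"),
                     mk_res(n = 120))
  for (b in base_cases) {
    worse_i2 <- b; worse_i2$I2 <- min(100, b$I2 + 30)
    expect_lte(lv(grade_quality(worse_i2)$quality),
               lv(grade_quality(b)$quality))
    worse_n <- b; worse_n$pooled$n_total <- 100L
    expect_lte(lv(grade_quality(worse_n)$quality),
               lv(grade_quality(b)$quality))
  }
})

test_that("meta_analyse_group pools a trial group end to end", {
  corp <- mini_corpus()
  mph <- Filter(function(t) t$drug == "methylphenidate", corp$trials)
  res <- meta_analyse_group(mph, row_of("adhd_symptoms"), group = "mph")
  expect_s3_class(res, "meta_result")
  expect_equal(res$k, 2)
  expect_true(res$quality %in% c("very_low", "low", "moderate", "high"))
  expect_null(meta_analyse_group(mph, row_of("insomnia")))
})
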