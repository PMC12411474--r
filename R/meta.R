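#' Effect estimates
#'
#' All effects are oriented so that *negative favors the intervention*: for
#' decrease-is-good continuous outcomes the standardized mean difference is
#' taken as intervention minus placebo; for increase-is-good outcomes the
#' sign is flipped; for dichotomous event-is-harm outcomes the log odds
#' ratio is positive when the intervention produces more events (harm).
#' Downstream, a 95% CI entirely below zero therefore always reads
#' "improves" and one entirely above zero "worsens".
#'
#' @param measure `"SMD"` or `"logOR"`.
#' @param value Point estimate (oriented as above).
#' @param se Standard error, `> 0`.
#' @param n_total Participants contributing to the estimate.
#' @param trial_id,risk_of_bias Provenance, carried for quality grading.
#' @return An `effect_estimate` with 95% Wald interval.
#' @export
effect_estimate <- function(measure, value, se, n_total,
                            trial_id = NA_character_,
                            risk_of_bias = NA_character_) {
  measure <- match.arg(measure, c("SMD", "logOR"))
  if (!is.finite(se) || se <= 0) stop("se must be finite and > 0")
  z <- qnorm(0.975)
  structure(list(measure = measure, value = value, se = se,
                 ci_low = value - z * se, ci_high = value + z * se,
                 n_total = as.integer(n_total), trial_id = trial_id,
                 risk_of_bias = risk_of_bias),
            class = "effect_estimate")
}

orient_sign <- function(outcome)
  switch(outcome$benefit_direction,
         "decrease-is-good" = 1, "increase-is-good" = -1,
         "event-is-harm" = 1, "event-is-good" = -1)

#' Trial-level effect for one outcome
#'
#' Continuous outcomes yield a standardized mean difference with the
#' small-sample (Hedges) correction `J = 1 - 3/(4*df - 1)`; dichotomous
#' outcomes a log odds ratio, with 0.5 added to every cell of the 2x2 table
#' when any cell is zero.  Effects are oriented per [effect_estimate()].
#'
#' @param trial A [trial_record()].
#' @param outcome One row of the outcome catalogue (data.frame or list with
#'   `outcome_id`, `scale`, `benefit_direction`).
#' @return An `effect_estimate`, or an `outcome_not_measured` marker when
#'   either arm lacks the outcome.
#' @examples
#' cat18 <- default_outcome_catalogue()
#' tr <- trial_record("t1", "methylphenidate", "stimulant-MPH",
#'   eligibility_criteria(6, 17),
#'   list(arm_summary("intervention", "methylphenidate", 100,
#'          events = c(seizures = 10L)),
#'        arm_summary("placebo", "placebo", 100,
#'          events = c(seizures = 5L))))
#' exp(arm_effect(tr, cat18[cat18$outcome_id == "seizures", ])$value)  # 2.111
#' @export
arm_effect <- function(trial, outcome) {
  oid <- outcome$outcome_id
  roles <- vapply(trial$arms, function(a) a$arm_role, character(1))
  ia <- trial$arms[[which(roles == "intervention")[1]]]
  pa <- trial$arms[[which(roles == "placebo")[1]]]
  sgn <- orient_sign(outcome)
  if (outcome$scale == "continuous") {
    ci <- ia$continuous[[oid]]; cp <- pa$continuous[[oid]]
    if (is.null(ci) || is.null(cp))
      return(structure(list(trial_id = trial$trial_id, outcome_id = oid,
                            reason = "outcome-not-measured"),
                       class = "outcome_not_measured"))
    n1 <- ia$n; n0 <- pa$n
    sp2 <- ((n1 - 1) * ci$sd^2 + (n0 - 1) * cp$sd^2) / (n1 + n0 - 2)
    if (sp2 <= 0) stop("zero variance in both arms for outcome '", oid, "'")
    d <- (ci$mean - cp$mean) / sqrt(sp2)
    J <- 1 - 3 / (4 * (n1 + n0 - 2) - 1)
    g <- sgn * J * d
    se <- sqrt((n1 + n0) / (n1 * n0) + g^2 / (2 * (n1 + n0)))
    effect_estimate("SMD", g, se, n1 + n0, trial$trial_id, trial$risk_of_bias)
  } else {
    e1 <- ia$events[[oid]]; e0 <- pa$events[[oid]]
    if (is.null(e1) || is.null(e0))
      return(structure(list(trial_id = trial$trial_id, outcome_id = oid,
                            reason = "outcome-not-measured"),
                       class = "outcome_not_measured"))
    a <- e1; b <- ia$n - e1; c_ <- e0; d_ <- pa$n - e0
    if (any(c(a, b, c_, d_) == 0)) {
      a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d_ <- d_ + 0.5
    }
    lor <- sgn * log((a * d_) / (b * c_))
    se <- sqrt(1/a + 1/b + 1/c_ + 1/d_)
    effect_estimate("logOR", lor, se, ia$n + pa$n,
                    trial$trial_id, trial$risk_of_bias)
  }
}

#' Heterogeneity statistics
#'
#' Cochran's Q against the fixed-effect pooled value, `I2 = max(0,
#' (Q - df)/Q) * 100`, and the DerSimonian-Laird moment estimator
#' `tau2 = max(0, (Q - df)/C)` with `C = sum(w) - sum(w^2)/sum(w)`.
#' A single effect returns all three as 0 by convention.
#'
#' @param effects List of `effect_estimate` objects.
#' @return List with `Q`, `I2`, `tau2`.
#' @export
heterogeneity_stats <- function(effects) {
  k <- length(effects)
  if (k < 2) return(list(Q = 0, I2 = 0, tau2 = 0))
  y <- vapply(effects, `[[`, numeric(1), "value")
  w <- 1 / vapply(effects, `[[`, numeric(1), "se")^2
  yf <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yf)^2)
  df <- k - 1
  C <- sum(w) - sum(w^2) / sum(w)
  list(Q = Q,
       I2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0,
       tau2 = max(0, (Q - df) / C))
}

#' Inverse-variance pooling
#'
#' Fixed-effect weights are `1/se^2`; the random-effects model adds the
#' DerSimonian-Laird `tau2` to every within-study variance.  With a single
#' study the pooled estimate is that study's estimate and `tau2 = 0`.
#'
#' @param effects List of `effect_estimate` objects sharing one measure.
#' @param model `"random"` (default) or `"fixed"`.
#' @param group,outcome_id Labels carried into the result.
#' @return A `meta_result`: `pooled` (an `effect_estimate`), `k`, `Q`, `I2`,
#'   `tau2`, `model`, the input `effects`, and (after [grade_quality()])
#'   `quality` and `downgrade_reasons`.
#' @export
pool_effects <- function(effects, model = c("random", "fixed"),
                         group = NA_character_, outcome_id = NA_character_) {
  model <- match.arg(model)
  if (!length(effects)) stop("no effects to pool")
  meas <- unique(vapply(effects, `[[`, character(1), "measure"))
  if (length(meas) > 1)
    stop("cannot pool mixed effect measures: ", paste(meas, collapse = ", "))
  het <- heterogeneity_stats(effects)
  y <- vapply(effects, `[[`, numeric(1), "value")
  v <- vapply(effects, `[[`, numeric(1), "se")^2
  n_total <- sum(vapply(effects, `[[`, integer(1), "n_total"))
  w <- if (model == "random") 1 / (v + het$tau2) else 1 / v
  pooled_val <- sum(w * y) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  structure(list(group = group, outcome_id = outcome_id, model = model,
                 pooled = effect_estimate(meas, pooled_val, pooled_se, n_total),
                 k = length(effects), Q = het$Q, I2 = het$I2,
                 tau2 = het$tau2, effects = effects,
                 quality = NA_character_, downgrade_reasons = list()),
            class = "meta_result")
}

#' GRADE thresholds
#'
#' @param rob_weight_fraction Downgrade for risk of bias when more than this
#'   fraction of the fixed-effect pooled weight comes from high-risk trials.
#' @param i2_moderate,i2_substantial I2 cut-points: one point lost above the
#'   first, two above the second.
#' @param ois Optimal information size: fewer total participants than this
#'   loses a point for imprecision.
#' @param decision_threshold_smd,decision_threshold_logor Clinical decision
#'   thresholds on the oriented effect scale; a CI crossing both the null
#'   and a threshold is imprecise.
#' @param model Default pooling model for the engine.
#' @export
grade_config <- function(rob_weight_fraction = 0.5,
                         i2_moderate = 50, i2_substantial = 75,
                         ois = 400,
                         decision_threshold_smd = 0.5,
                         decision_threshold_logor = log(1.25),
                         model = "random") {
  list(rob_weight_fraction = rob_weight_fraction,
       i2_moderate = i2_moderate, i2_substantial = i2_substantial,
       ois = ois, decision_threshold_smd = decision_threshold_smd,
       decision_threshold_logor = decision_threshold_logor,
       model = model)
}

quality_levels <- c("very_low", "low", "moderate", "high")

#' Grade the quality of pooled evidence
#'
#' Starts at `high` (4 points) and downgrades: one point for risk of bias
#' when high-risk trials dominate the pooled weight; one (two) points for
#' heterogeneity when I2 exceeds the moderate (substantial) cut; one point
#' for imprecision when the sample is below the optimal information size or
#' the CI crosses both the null and the decision threshold.  Floors at
#' `very_low`.
#'
#' @param result A `meta_result` from [pool_effects()].
#' @param config A [grade_config()].
#' @return The `meta_result` with `quality` and `downgrade_reasons`
#'   (named list of points lost) filled in.
#' @export
grade_quality <- function(result, config = grade_config()) {
  reasons <- list()
  w <- 1 / vapply(result$effects, `[[`, numeric(1), "se")^2
  rob <- vapply(result$effects, `[[`, character(1), "risk_of_bias")
  frac_high <- sum(w[rob == "high"]) / sum(w)
  if (!is.na(frac_high) && frac_high > config$rob_weight_fraction)
    reasons$risk_of_bias <- 1L
  if (result$I2 > config$i2_substantial) {
    reasons$heterogeneity <- 2L
  } else if (result$I2 > config$i2_moderate) {
    reasons$heterogeneity <- 1L
  }
  p <- result$pooled
  thr <- if (p$measure == "SMD") config$decision_threshold_smd
         else config$decision_threshold_logor
  crosses_null <- p$ci_low < 0 && p$ci_high > 0
  crosses_thr <- p$ci_low < -thr || p$ci_high > thr
  if (p$n_total < config$ois || (crosses_null && crosses_thr))
    reasons$imprecision <- 1L
  lost <- sum(unlist(reasons))
  result$quality <- quality_levels[max(1, 4 - lost)]
  result$downgrade_reasons <- reasons
  result
}

#' Meta-analyse one trial group for one outcome
#'
#' Convenience wrapper: computes per-trial effects (skipping trials that do
#' not measure the outcome), pools them under the configured model and
#' grades the result.  Returns `NULL` when no trial measures the outcome.
#'
#' @param trials List of [trial_record()]s (one pooling group).
#' @param outcome One catalogue row.
#' @param group Group key label.
#' @param config A [grade_config()].
#' @export
meta_analyse_group <- function(trials, outcome, group = NA_character_,
                               config = grade_config()) {
  effs <- lapply(trials, arm_effect, outcome = outcome)
  effs <- Filter(function(e) inherits(e, "effect_estimate"), effs)
  if (!length(effs)) return(NULL)
  res <- pool_effects(effs, model = config$model, group = group,
                      outcome_id = outcome$outcome_id)
  grade_quality(res, config)
}
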