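---
title: "metarec: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metarec: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metarec)
```

`metarec` automates the evidence-to-decision steps a guideline panel
performs — PICO formulation, meta-analysis, quality grading, risk–benefit
judgment, recommendation strength — for a single ADHD patient at a time,
and provides the statistics needed to compare such a recommender against
encoded clinical practice guidelines.  This vignette documents the model
and every place where the design was genuinely open.

## 1. The decision model

### Preferences and criticality

Both raters score each of 18 catalogue outcomes on a 1–9 importance scale;
scores at or above the threshold (default **7**) are *critical*.  The
threshold is a parameter of `mark_critical()`, not a constant.  Two
combination rules are supported: *comprehensive* (union of the two critical
sets) and *conjoint* (intersection).  A conjoint combination may be empty,
in which case the engine returns a typed `no-critical-preferences` status
rather than an error — silence, not a crash, is the correct clinical
behavior.  Missing ratings are treated as non-critical with a warning; we
do not impute.  An optional `max_critical` cap exists for settings where
raters are asked to be more discriminating, but the default is uncapped
with only a floor of one critical outcome warned about.

The packaged catalogue is **provisional**: the named entries (ADHD symptom
improvement, clinical impression, quality of life, academic performance;
seizures, vasovagal syncope, appetite decrease, …) are fixed, and the
remainder are placeholders chosen from the standard ADHD trial adverse-event
vocabulary to complete the 18.  Treatment discontinuation is modeled as an
always-evaluated dichotomous outcome *and* is ratable, since the decision
rule names it separately from the critical safety outcomes.

### Eligibility and pooling levels

The pooling ladder instantiates "criteria relax as the level rises" as a
concrete, overridable configuration:

| level | strictness | grouping | strictness meaning |
|---|---|---|---|
| L1 | strict  | drug + dose | full criteria: age range, sex, excluded comorbidities and co-treatments, severity threshold |
| L2 | strict  | drug | same criteria, doses pooled |
| L3 | relaxed | drug | age band (child/adolescent < 18 vs adult) + excluded comorbidities |
| L4 | minimal | drug class | age band only |

Each rung's (strictness, grouping) pair can be overridden in
`pooling_level()`, including pooling L4 by drug rather than class.
Eligibility is monotone by construction: the strict criteria set contains
the relaxed set contains the minimal set, which the test suite checks as a
property.  Trials with flexible dosing form their own `"flexible"` dose
bucket at L1.  When a trial has a severity threshold but the patient record
carries no severity score, the criterion is skipped with a warning rather
than silently passed or failed.

### Effect measures and pooling

The corpus stores arm-level summaries only (no individual-level data):
change-from-baseline mean/sd for continuous outcomes (endpoint summaries
allowed with a per-trial flag) and event counts for dichotomous ones.
Continuous outcomes yield a standardized mean difference with the Hedges
small-sample correction $J = 1 - 3/(4\,df - 1)$ and the standard SE
$\sqrt{(n_1+n_0)/(n_1 n_0) + g^2/(2(n_1+n_0))}$; dichotomous outcomes yield
a log odds ratio with 0.5 added to all four cells when any cell is zero.
These measures are not named by the clinical source material; they are the
standard choices of the ADHD meta-analysis literature.

**Orientation convention.** Every effect is oriented so *negative favors
the intervention*: decrease-is-good scales keep their sign,
increase-is-good scales are flipped, and harm events keep log OR > 0 as
harm.  One convention everywhere means the verdict rule is a single CI
comparison and cannot be applied inconsistently per outcome.

Pooling is inverse-variance; the default model is random effects with the
DerSimonian–Laird moment estimator
$\tau^2 = \max(0, (Q - df)/C)$, $C = \sum w - \sum w^2 / \sum w$, and
$I^2 = \max(0, (Q - df)/Q) \cdot 100$.  A single study pools to itself with
$Q = I^2 = \tau^2 = 0$ by convention and is then exposed to the imprecision
check like any other result.  Fixed-effect pooling is available via
`grade_config(model = "fixed")`.

### Quality grading

Quality starts at *high* (4 rungs: high / moderate / low / very_low) and is
downgraded:

* **risk of bias** (−1): more than 50% of the fixed-effect pooled weight
  comes from high-risk-of-bias trials.  Risk of bias is a 3-level trial
  attribute (low / some-concerns / high); no per-domain structure is
  modeled because none is available upstream.
* **heterogeneity** (−1 / −2): I² above 50 / above 75.
* **imprecision** (−1): total participants below the optimal information
  size (default 400), or the 95% CI crosses both the null and the decision
  threshold (default |SMD| 0.5, OR 1.25).

All thresholds live in `grade_config()` with the stated defaults; they are
conventional GRADE practice rather than prescribed values.  Publication
bias and indirectness are deliberately not implemented.  Outcome-level
quality (4 rungs) maps onto judgment-level quality (3 rungs) by collapsing
low and very_low.

### Risk–benefit judgment and strength

Over the critical outcomes with available evidence (discontinuation always
included when measured):

* **favorable** — a *strict* majority of critical efficacy outcomes
  improve, and no safety/discontinuation outcome worsens;
* **unfavorable** — not a majority, and at least one safety or
  discontinuation outcome worsens;
* **neutral** — every other case.

Design choices the rule text leaves open, fixed here: "majority" means
strictly more than half of the critical efficacy outcomes *with available
evidence* (outcomes no trial measured leave the denominator, noted in the
report); an exact half is not a majority; no critical efficacy evidence at
all is neutral with an `insufficient-evidence` flag.  The test suite checks
the implementation against an exhaustively enumerated truth-table oracle on
all verdict grids up to 4 × 4.

Direction follows the judgment (for / against / none) and strength is
strong iff the judgment quality is high or moderate — a single quality
channel; imprecision influences strength only through quality.  This
mapping reproduces the observed behavior that low-quality evidence yields
uniformly weak recommendations.

## 2. Guideline encodings

The five CPG comparators are first-match-wins rulesets shipped as editable
JSON (`inst/extdata/guidelines/`).  Fidelity is approximate and versioned:
each encodes a first-line drug set by age band plus a non-stimulant second
line triggered by a stimulant contraindication.  The condition that makes
one cohort member in ~32 receive the minority set is not documented in the
source material; the packaged encoding provisionally uses psychosis or
cardiovascular comorbidity, or a prior serious adverse event to a
stimulant.  "Against" recommendations are not modeled, as CPGs do not
report them consistently.

## 3. Comparison statistics

* **Blau's index** $1 - \sum p_i^2$ over *distinct recommendation sets*
  (exact set equality, the empty set its own category).  Sets, not drugs,
  are the category unit so that the index matches the "number of distinct
  recommendations" view; drug-level diversity can be computed by passing
  per-drug counts directly.
* **Overlap concordance**: a patient overlaps iff the two systems share at
  least one recommended drug; denominators are all patients or only
  patients with a non-empty favorable set.  When no non-favorable patient
  overlaps, `all = favorable_only × favorable fraction` — an identity the
  tests verify.  An empty set never overlaps, not even with itself.
* **Pharmacological distance**: profiles carry neurotransmitter targets,
  modes of action, chemical family and enantiomer/prodrug/salt relations.
  Distance = 10 per target mismatch + 2 per mode mismatch + 5 for a family
  mismatch + 1 per relation step, no-treatment fixed at 33.  The weights
  are the exact solution of the five published anchor distances from
  methylphenidate (1, 7, 15, 19, 33) — solved on paper before
  implementation, then machine-checked.  Mismatches are weighted equally
  across targets (a serotonergic drug is as far from a dopaminergic one as
  from a noradrenergic one); per-target weights would be a config extension.
* **Set-to-set distance**: the aggregation from drug-level distance to
  recommender-level dissimilarity is not specified upstream; we use the
  modified-Hausdorff average (mean of the two directed mean-of-minima),
  which is symmetric, bounded by 33, reduces to the drug distance for
  singletons, and is zero iff the sets are equal.  Empty sets are replaced
  by `{no_treatment}`.
* **UPGMA**: average linkage, implemented in-package because deterministic
  tie-breaking (lexicographically smallest pair of cluster representatives)
  is required for reproducible trees; `stats::hclust` is the independent
  oracle on tie-free matrices.  Newick serialization via `ape`.

## 4. The synthetic world

The generators state one world and keep it:

* **Cohort marginals** follow the published pediatric cohort: ages 6–17,
  65.6% male, 78.1% combined / 21.9% inattentive subtype, severity
  ~N(34.4, 6), the published comorbidity frequencies, 46.9% in
  psychotherapy.
* **Preferences** come from a discretized latent-Gaussian model.  Per case
  and outcome, patient and clinician latents share a common factor with
  correlation `agreement`.  The marginal criticality probability is exactly
  `p_critical` per rater by construction of the score bins.  The defaults
  (`p_critical = 4.8/18`, `agreement = 0.7754`) were calibrated *once,
  analytically* (a one-dimensional Gaussian integral solved with
  `uniroot`) so that the per-rater mean (4.8), union mean (6.4) and
  intersection mean (3.2) of critical counts match the published Study-2
  marginals in expectation.  No parameter was adjusted after seeing test
  results.
* **Trials** draw sample means, sds (scaled χ²) and binomial event counts
  from configured truths: oriented SMDs for continuous outcomes, odds
  ratios with a placebo-arm risk `p0` for dichotomous ones.  Placebo
  response is −4 points (sd 10) on decrease-is-good scales, +2 (sd 8) on
  increase-is-good scales — typical magnitudes for ADHD symptom and
  functioning scales.
* The `favorable_drug` fixture gives the beneficial drug SMD −0.8 on every
  efficacy outcome and a *neutral-to-mildly-protective* safety profile
  (OR 0.9).  A literal OR of 1.0 would be "no harm" only in expectation:
  any finite corpus then worsens some safety outcome with ≈ 2.5%
  probability per outcome, flipping favorable patients for reasons that
  are sampling noise, not signal.  OR 0.9 makes "no harm" true with high
  probability in every realized corpus while remaining clinically
  indistinguishable from no effect.  Every fixture member rates ADHD
  symptom improvement as critical (9/9), since a patient with no critical
  efficacy outcome cannot, by the decision rule, receive any
  recommendation.  The harmful drug has SMD 0 on all efficacy outcomes and
  OR 2.5 on treatment discontinuation.

What the generators do **not** emulate: dose-ranging and crossover designs,
attrition, outcome reporting bias, correlated outcomes within trials, and
secular trends in the evidence base.  A green end-to-end test therefore
establishes that the pipeline recovers configured truths from well-behaved
arm-level data — not that it is robust to the pathologies of real trial
reports.

## 5. Numerical and formatting choices

Wald 95% intervals throughout; ties in UPGMA broken lexicographically;
`tau2` and `I2` truncated at zero when `Q ≤ df`; continuity correction only
when a cell is zero (all four cells corrected together); report rounding is
two decimals for Blau and one decimal for percentages, matching the
reporting precision of the comparison tables; JSON writing uses full
precision (`digits = NA`).  Corpus round-trips (JSON and CSV bundle) are
the identity and are tested field by field.

## 6. Known limitations

Only placebo-controlled two-arm comparisons are supported (no network
meta-analysis, no drug combinations); guideline encodings are approximate
by construction; the 18-outcome catalogue is partly provisional; no
publication-bias or indirectness downgrades; recommendation strength uses a
single quality channel.  The engine's validity range for age is 6–65.
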