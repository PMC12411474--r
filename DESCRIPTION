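Package: metarec
Title: Automated Evidence-Based Treatment Recommendations for ADHD
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A clinical decision engine that generates personalized,
    participatory, GRADE-style treatment recommendations for ADHD from a
    structured corpus of randomized controlled trials: patient-trial
    eligibility matching at four pooling levels, random-effects
    meta-analysis per intervention and patient-critical outcome, evidence
    quality grading with downgrade reasons, and rule-based risk-benefit
    judgments mapped to directed, strength-rated recommendations.  Also
    provides the comparison toolkit used to benchmark such recommenders
    against clinical practice guidelines: Blau diversity of recommendation
    sets, overlap concordance, a pharmacological distance derived from
    neuroscience-based nomenclature drug profiles, and UPGMA dendrograms
    over recommender systems.  Includes seeded synthetic generators for
    evidence corpora and patient cohorts so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
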