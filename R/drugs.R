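#' Drug registry and pharmacological profiles
#'
#' The registry maps drug codes to display names, pharmacological classes
#' (used for pooling-level L4 grouping) and regulatory approval flags.  The
#' profile table captures, in the style of neuroscience-based nomenclature,
#' each drug's neurotransmitter targets, modes of action, chemical family
#' and direct relations (enantiomer / prodrug / salt mixture) to other
#' compounds; profiles drive the pharmacological distance used when
#' comparing recommender systems.
#'
#' `"no_treatment"` is a reserved profile standing for the absence of
#' pharmacological treatment; its distance to every active drug is the
#' scheme maximum.
#'
#' @return `default_drug_registry()`: a data.frame with columns `drug`,
#'   `name`, `class`, `approved_adhd`.  `default_drug_profiles()`: a named
#'   list of profiles, each with `targets`, `modes`, `family` and
#'   `relations` (named character vector, e.g.
#'   `c(enantiomer_of = "methylphenidate")`).
#' @examples
#' reg <- default_drug_registry()
#' reg[reg$class == "alpha2-agonist", ]
#' @export
default_drug_registry <- function() {
  d <- function(drug, name, class, approved)
    data.frame(drug = drug, name = name, class = class,
               approved_adhd = approved)
  reg <- rbind(
    d("methylphenidate",        "Methylphenidate",        "stimulant-MPH", TRUE),
    d("dexmethylphenidate",     "Dexmethylphenidate",     "stimulant-MPH", TRUE),
    d("serdexmethylphenidate",  "Serdexmethylphenidate",  "stimulant-MPH", TRUE),
    d("amphetamine",            "Amphetamine",            "stimulant-AMP", TRUE),
    d("dexamphetamine",         "Dexamphetamine",         "stimulant-AMP", TRUE),
    d("lisdexamfetamine",       "Lisdexamfetamine",       "stimulant-AMP", TRUE),
    d("mixed_amphetamine_salts","Mixed amphetamine salts","stimulant-AMP", TRUE),
    d("atomoxetine",            "Atomoxetine",            "nonstimulant-NRI", TRUE),
    d("viloxazine",             "Viloxazine",             "nonstimulant-NRI", TRUE),
    d("guanfacine",             "Guanfacine",             "alpha2-agonist", TRUE),
    d("clonidine",              "Clonidine",              "alpha2-agonist", TRUE),
    d("bupropion",              "Bupropion",              "other", FALSE),
    d("modafinil",              "Modafinil",              "other", FALSE),
    d("no_treatment",           "No treatment",           "none", FALSE)
  )
  rownames(reg) <- NULL
  reg
}

#' @rdname default_drug_registry
#' @export
default_drug_profiles <- function() {
  p <- function(targets, modes, family, relations = character(0))
    list(targets = targets, modes = modes, family = family,
         relations = relations)
  list(
    methylphenidate = p(c("dopamine", "norepinephrine"),
                        "reuptake_inhibitor", "phenidate"),
    dexmethylphenidate = p(c("dopamine", "norepinephrine"),
                           "reuptake_inhibitor", "phenidate",
                           c(enantiomer_of = "methylphenidate")),
    serdexmethylphenidate = p(c("dopamine", "norepinephrine"),
                              "reuptake_inhibitor", "phenidate",
                              c(prodrug_of = "dexmethylphenidate")),
    amphetamine = p(c("dopamine", "norepinephrine"),
                    c("reuptake_inhibitor", "releaser"), "phenethylamine"),
    dexamphetamine = p(c("dopamine", "norepinephrine"),
                       c("reuptake_inhibitor", "releaser"), "phenethylamine",
                       c(enantiomer_of = "amphetamine")),
    lisdexamfetamine = p(c("dopamine", "norepinephrine"),
                         c("reuptake_inhibitor", "releaser"),
                         "phenethylamine",
                         c(prodrug_of = "dexamphetamine")),
    mixed_amphetamine_salts = p(c("dopamine", "norepinephrine"),
                                c("reuptake_inhibitor", "releaser"),
                                "phenethylamine",
                                c(salt_of = "amphetamine")),
    atomoxetine = p("norepinephrine", "reuptake_inhibitor",
                    "phenoxypropylamine"),
    viloxazine = p("norepinephrine", "reuptake_inhibitor", "morpholine"),
    guanfacine = p("norepinephrine", "receptor_agonist", "phenylacetamide"),
    clonidine = p("norepinephrine", "receptor_agonist", "imidazoline"),
    bupropion = p(c("dopamine", "norepinephrine"),
                  c("reuptake_inhibitor", "releaser"), "aminoketone"),
    modafinil = p("dopamine", "reuptake_inhibitor", "benzhydryl"),
    no_treatment = p(character(0), character(0), "none")
  )
}
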