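{
  "guideline_id": "AAP",
  "version": "metarec-encoding-1 (provisional approximation)",
  "rules": [
    {
      "label": "stimulant contraindicated (comorbidity): non-stimulants only",
      "when": {"comorbidity_any": ["psychosis", "cardiovascular_disease"]},
      "drugs": ["atomoxetine", "clonidine", "guanfacine"]
    },
    {
      "label": "stimulant contraindicated (serious AE history): non-stimulants only",
      "when": {"serious_ae_any": ["methylphenidate", "dexamphetamine", "lisdexamfetamine"]},
      "drugs": ["atomoxetine", "clonidine", "guanfacine"]
    },
    {
      "label": "first line: stimulants and non-stimulants",
      "when": {},
      "drugs": ["methylphenidate", "dexmethylphenidate", "dexamphetamine",
                "lisdexamfetamine", "mixed_amphetamine_salts",
                "atomoxetine", "clonidine", "guanfacine"]
    }
  ]
}
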