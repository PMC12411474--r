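{
  "guideline_id": "NICE",
  "version": "metarec-encoding-1 (provisional approximation)",
  "rules": [
    {
      "label": "stimulant contraindicated (comorbidity): non-stimulant second line",
      "when": {"comorbidity_any": ["psychosis", "cardiovascular_disease"]},
      "drugs": ["atomoxetine", "guanfacine"]
    },
    {
      "label": "stimulant contraindicated (serious AE history): non-stimulant second line",
      "when": {"serious_ae_any": ["methylphenidate", "dexamphetamine", "lisdexamfetamine"]},
      "drugs": ["atomoxetine", "guanfacine"]
    },
    {
      "label": "first line",
      "when": {},
      "drugs": ["methylphenidate"]
    }
  ]
}
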