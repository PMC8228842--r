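{
  "comment": "Default clinical grouping of the 21 past-disease flags by organ system, and the set of diseases counted as having a very severe course (severe invasive infections). Both are configurable.",
  "groups": {
    "pulmonology": ["pneumonia", "bronchitis", "bronchiectasis", "laryngitis"],
    "otorhinolaryngology": ["otitis", "sinusitis", "urti", "stomatitis", "conjunctivitis"],
    "gastroenterology": ["diarrhea", "ibd", "ascariasis"],
    "rheumatology": ["arthritis", "guillain_barre"],
    "resistance": ["sepsis", "meningitis", "encephalitis", "abscess", "furunculosis", "uti", "hemophilia_a"]
  },
  "severe": ["sepsis", "meningitis", "encephalitis", "pneumonia"]
}
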