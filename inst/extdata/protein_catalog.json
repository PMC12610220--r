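{
  "comment": "Protein-source catalog: DIAAS values compiled from the literature (null = no reliable published value used), limiting-amino-acid groups, and label synonyms matched case-insensitively in listing order.",
  "entries": [
    {"source": "soy", "diaas": 0.91, "limiting_group": "legume_SAA_His",
     "synonyms": ["soy protein", "soya protein", "soy flour", "textured soy", "soy isolate", "soy concentrate"]},
    {"source": "pea", "diaas": 0.65, "limiting_group": "legume_SAA_His",
     "synonyms": ["pea protein", "textured pea"]},
    {"source": "wheat", "diaas": 0.45, "limiting_group": "cereal_Lys_Thr_Trp",
     "synonyms": ["wheat gluten", "wheat protein", "seitan"]},
    {"source": "sunflower", "diaas": 0.60, "limiting_group": "other",
     "synonyms": ["sunflower protein"]},
    {"source": "faba_bean", "diaas": 0.55, "limiting_group": "legume_SAA_His",
     "synonyms": ["faba bean protein", "fava bean protein", "field bean protein"]},
    {"source": "potato", "diaas": null, "limiting_group": "none",
     "synonyms": ["potato protein"]},
    {"source": "rice", "diaas": 0.60, "limiting_group": "cereal_Lys_Thr_Trp",
     "synonyms": ["rice protein"]},
    {"source": "lupin", "diaas": 0.65, "limiting_group": "legume_SAA_His",
     "synonyms": ["lupin protein", "lupine protein"]},
    {"source": "chickpea", "diaas": 0.70, "limiting_group": "legume_SAA_His",
     "synonyms": ["chickpea protein", "chick pea protein"]},
    {"source": "mung_bean", "diaas": 0.70, "limiting_group": "legume_SAA_His",
     "synonyms": ["mung bean protein"]}
  ]
}
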