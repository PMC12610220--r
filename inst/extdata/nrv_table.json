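{
  "comment": "EU Regulation 1169/2011 Annex XIII nutrient reference values used for label %-coverage.",
  "entries": [
    {"nutrient": "vitamin_b12", "nrv": 4.0, "unit": "ug"},
    {"nutrient": "iron", "nrv": 14.0, "unit": "mg"},
    {"nutrient": "zinc", "nrv": 10.0, "unit": "mg"},
    {"nutrient": "vitamin_b2", "nrv": 1.4, "unit": "mg"},
    {"nutrient": "vitamin_d", "nrv": 5.0, "unit": "ug"},
    {"nutrient": "iodine", "nrv": 150.0, "unit": "ug"}
  ]
}
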