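{
  "comment": "Additive lexicon: label tokens and E-numbers mapped to functional classes. Constructed from the additive classes and named examples of the product survey plus common EU food additives; editable superset, not the survey's verbatim appendix list.",
  "entries": [
    {"token": "methylcellulose", "e_number": "E461", "functional_class": "thickener"},
    {"token": "hydroxypropyl methylcellulose", "e_number": "E464", "functional_class": "thickener"},
    {"token": "carboxymethylcellulose", "e_number": "E466", "functional_class": "thickener"},
    {"token": "cellulose", "e_number": "E460", "functional_class": "thickener"},
    {"token": "carrageenan", "e_number": "E407", "functional_class": "thickener"},
    {"token": "xanthan gum", "e_number": "E415", "functional_class": "thickener"},
    {"token": "guar gum", "e_number": "E412", "functional_class": "thickener"},
    {"token": "locust bean gum", "e_number": "E410", "functional_class": "thickener"},
    {"token": "konjac", "e_number": "E425", "functional_class": "thickener"},
    {"token": "pectin", "e_number": "E440", "functional_class": "thickener"},
    {"token": "agar", "e_number": "E406", "functional_class": "thickener"},
    {"token": "gellan gum", "e_number": "E418", "functional_class": "thickener"},
    {"token": "sodium alginate", "e_number": "E401", "functional_class": "thickener"},
    {"token": "diphosphates", "e_number": "E450", "functional_class": "stabilizer"},
    {"token": "triphosphates", "e_number": "E451", "functional_class": "stabilizer"},
    {"token": "calcium chloride", "e_number": "E509", "functional_class": "stabilizer"},
    {"token": "potassium chloride", "e_number": "E508", "functional_class": "stabilizer"},
    {"token": "citric acid", "e_number": "E330", "functional_class": "acid_regulator"},
    {"token": "trisodium citrate", "e_number": "E331", "functional_class": "acid_regulator"},
    {"token": "lactic acid", "e_number": "E270", "functional_class": "acid_regulator"},
    {"token": "acetic acid", "e_number": "E260", "functional_class": "acid_regulator"},
    {"token": "malic acid", "e_number": "E296", "functional_class": "acid_regulator"},
    {"token": "sodium carbonate", "e_number": "E500", "functional_class": "acid_regulator"},
    {"token": "paprika extract", "e_number": "E160c", "functional_class": "colorant"},
    {"token": "beetroot red", "e_number": "E162", "functional_class": "colorant"},
    {"token": "carotene", "e_number": "E160a", "functional_class": "colorant"},
    {"token": "curcumin", "e_number": "E100", "functional_class": "colorant"},
    {"token": "iron oxide", "e_number": "E172", "functional_class": "colorant"},
    {"token": "riboflavin colour", "e_number": "E101", "functional_class": "colorant"},
    {"token": "potassium sorbate", "e_number": "E202", "functional_class": "preservative"},
    {"token": "sorbic acid", "e_number": "E200", "functional_class": "preservative"},
    {"token": "sodium benzoate", "e_number": "E211", "functional_class": "preservative"},
    {"token": "sodium nitrite", "e_number": "E250", "functional_class": "preservative"},
    {"token": "sodium acetate", "e_number": "E262", "functional_class": "preservative"},
    {"token": "lecithin", "e_number": "E322", "functional_class": "emulsifier"},
    {"token": "mono- and diglycerides", "e_number": "E471", "functional_class": "emulsifier"},
    {"token": "polysorbate 80", "e_number": "E433", "functional_class": "emulsifier"},
    {"token": "ascorbic acid", "e_number": "E300", "functional_class": "antioxidant"},
    {"token": "sodium ascorbate", "e_number": "E301", "functional_class": "antioxidant"},
    {"token": "tocopherol", "e_number": "E306", "functional_class": "antioxidant"},
    {"token": "rosemary extract", "e_number": "E392", "functional_class": "antioxidant"},
    {"token": "monosodium glutamate", "e_number": "E621", "functional_class": "other"},
    {"token": "titanium dioxide", "e_number": "E171", "functional_class": "colorant"},
    {"token": "glucono-delta-lactone", "e_number": "E575", "functional_class": "acid_regulator"},
    {"token": "calcium sulphate", "e_number": "E516", "functional_class": "stabilizer"},
    {"token": "tara gum", "e_number": "E417", "functional_class": "thickener"}
  ]
}
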