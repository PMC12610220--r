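Package: labelprofiler
Title: Label-Based Nutritional Profiling of Plant-Based Meat and Sausage Analogues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for evaluating the nutritional quality of retail plant-based
    meat and sausage analogues against animal-based reference products from
    per-100 g label declarations. Implements label-value parsing with
    upper-bound ("<x") handling, fibre imputation from energy differences, the
    2023 FSAm-NPS point algorithm and Nutri-Score grading with red-meat protein
    capping and preparation-salt adjustment, DIAAS-based protein-quality
    classification from ingredient lists, micronutrient fortification and
    additive annotation, and a category-level comparison layer (Mann-Whitney U
    with Bonferroni correction, scaled PCA, two-group PERMANOVA on Euclidean
    distances). A seeded synthetic cohort generator reproduces configurable
    per-subcategory nutrient distributions so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
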