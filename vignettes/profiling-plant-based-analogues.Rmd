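---
title: "Methods: label-based nutritional profiling of plant-based meat and sausage analogues"
author: "labelprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-based nutritional profiling of plant-based meat and sausage analogues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labelprofiler)
```

## The problem and the data model

Retail plant-based meat and sausage analogues (PBMAs) — burgers, schnitzels,
bratwurst, salami and the like built from isolated or concentrated plant
proteins — are routinely compared against the animal products they imitate.
Because laboratory composition analysis is expensive, such comparisons are
usually made from the mandatory per-100 g label declaration (EU Regulation
1169/2011): energy in kJ and kcal, fat, saturated fat, carbohydrates, sugars,
protein and salt, with fibre declared voluntarily, plus the free-text
ingredient list and any declared fortificants.

`labelprofiler` models one product as a row of a validated table: identity,
study arm (plant/animal), one of nine subcategories (four meat: minced,
chicken-style, breaded, red meat; five sausage: bratwurst, cooked sausage,
salami, ham/bacon, spreadable), the nutrient panel, ingredient text,
fortificant declarations, and two Nutri-Score modifier flags. Three labelling
quirks are handled at parse time:

* **Upper-bound declarations.** Trace amounts are printed as `"<0.5 g"`. The
  package records the bound itself (0.5) and keeps a per-nutrient flag so a
  sensitivity analysis can substitute, say, half the bound.
* **Decimal commas** are accepted on input; all output uses decimal points.
* **Missing fibre** is imputed from the energy the other macronutrients do
  not account for, with the statutory conversion factors (kJ/g: fat 37,
  carbohydrate 17, protein 17, fibre 8):
  \[ \hat f = \max\!\big(0,\; (E_{kJ} - 37\,\mathrm{fat} - 17\,\mathrm{cho}
      - 17\,\mathrm{protein})/8 \big). \]
  The estimate is flagged unreliable when the raw residual is negative or
  implies more fibre than carbohydrate + 2 g. Unreliable imputations are
  excluded from fibre summary statistics but retained for scoring, where a
  fibre quantity is required and 0 is its floor.

The canonical energy unit is kJ (primary under the EU regulation); kcal is
derived with 4.184 kJ/kcal. Validation enforces non-negativity,
saturated fat ≤ fat, sugar ≤ carbohydrate, and kJ/kcal agreement within 2%.

## The FSAm-NPS score and Nutri-Score grades

The core algorithm is the 2023 revision of the FSAm-NPS point system for
general foods, the basis of the Nutri-Score front-of-pack label. Unfavourable
components earn points — energy (0–10), saturated fat (0–10), sugars (0–15),
salt (0–20) — and favourable components subtract points — protein (0–7),
fibre (0–5) and the fruits/vegetables/legumes (FVL) share (0/1/2/5). Each
component is a monotone step function with *strict* thresholds (`value > t`
earns the point); the tables live in one versioned data structure
(`nutri_thresholds()`), exportable as JSON, so a future revision is a data
change. With \(N\) the unfavourable and \(P\) the favourable sum, the total
score is \(N - P\), spanning −17 (best) to +55 (worst); `score_bounds()`
verifies the span by exhaustive boundary enumeration (all \(2^7\)
combinations of component-zero and component-saturating inputs). Grades:
A ≤ 0, B 1–2, C 3–10, D 11–18, E ≥ 19.

Three scoring adaptations reflect how the underlying product survey applied
the algorithm:

* **Protein gating.** Protein points count only when \(N < 11\) or the FVL
  component reaches its 5-point maximum.
* **Red-meat cap.** For red meat and products derived from it, counted
  protein points are capped at 2. By default the flag is on for animal-arm
  minced meat, red meat, bratwurst, cooked sausage, salami, ham/bacon and
  spreadable sausage (pork/beef products), off for chicken, breaded and all
  plant products; it is configurable per product.
* **Preparation salt.** Products customarily salted during preparation
  (animal-arm minced and red meat by default) are scored at declared salt
  + 0.5 g/100 g.
* **FVL = 0.** The FVL component is implemented but the pipeline passes 0 for
  every product: protein-isolate analogues contain no minimally processed
  FVL fraction, and the component only scores above 40%. The −17 bound is
  therefore a property of the algorithm, not reachable by pipeline inputs.

Whether imputed (rather than declared) fibre should enter scoring is a
genuinely open choice; the package scores with it — a product is not
penalised for a voluntary omission — and carries the provenance flag in every
score row so the alternative is one filter away.

## Protein quality

Protein sources are extracted from the ingredient list by case-insensitive
synonym matching in listing order (the first match is the product's main
source). Each catalog source carries a DIAAS value where the literature
provides one (soy 0.91) and a limiting-amino-acid group: legumes are short on
sulphur amino acids and histidine, cereals on lysine, threonine and
tryptophan, potato protein has no limiting amino acid. A product demonstrates
*good* protein quality when, in order of precedence,

1. a source has known DIAAS ≥ 0.75 (the usual "good source" cutoff — soy
   qualifies, pea and wheat do not), or
2. its sources span both the legume and the cereal limiting group
   (complementary combination), or
3. a source has no limiting amino acids.

Otherwise the verdict is "not demonstrated". Relative ingredient proportions
are ignored (they are not declared). Two deliberate conservatisms: potato
protein is shipped with an *unknown* DIAAS — published values are sparse for
the isolates actually used — so it classifies through rule 3; and sunflower
protein is grouped "other" (lysine-limited but not a cereal profile), so
sunflower + legume does **not** form a complementary pair. The 0.75 cutoff
and all catalog values are data (JSON), not code.

## Fortification and additives

Fortificant declarations (`"vitamin_b12=1.0ug;iron=2.1mg"`) are parsed and
converted to percent coverage of the EU nutrient reference values
(B12 4.0 µg, iron 14 mg, zinc 10 mg, riboflavin 1.4 mg, vitamin D 5 µg,
iodine 150 µg). Iron that appears in the nutrition declaration but not in the
ingredient list is annotated as naturally occurring, not added. Additives are
matched per comma-separated ingredient segment against a lexicon of tokens
and E-numbers grouped by functional class; longer tokens suppress substrings
("methylcellulose" does not also count "cellulose"), duplicate mentions count
once, flavouring mentions are flagged separately and never counted as
additives, and paprika extract counts as a colorant only when its colouring
function is stated in the same segment ("colouring paprika extract"). The
shipped lexicon is a constructed superset assembled from the survey's named
examples and common EU additives; it is editable JSON.

## The comparison layer

All group comparisons are non-parametric, matching how such label data are
analysed (normality fails for every nutrient):

* **Mann–Whitney U**, two-sided, midrank ties. For pooled sizes ≤ 10 the
  p-value is exact by enumeration of all labelings (valid under ties);
  otherwise the normal approximation with tie-corrected variance and
  continuity correction is used. Bonferroni adjustment multiplies by an
  explicit family size — by default the nine subcategory comparisons within
  each nutrient, switchable to a per-cell family because the choice is
  ambiguous in practice.
* **PCA** on centred, unit-variance columns (via `prcomp`), reporting
  variance shares and per-variable contributions (squared loadings). Fibre is
  excluded from the feature matrix: it is near-absent in animal products and
  of low variability among analogues, so it would only add a trivial
  plant/animal indicator. Energy enters once, on the kcal scale.
* **Two-group PERMANOVA** on Euclidean distances of the scaled features:
  pseudo-\(F = (SS_B/1)/(SS_W/(n-2))\) computed from the squared distance
  matrix, \(R^2 = SS_B/SS_T\), and
  \(p = (\#\{F_{perm} \ge F_{obs}\} + 1)/(n_{perm}+1)\) over seeded label
  permutations (9,999 by default, sampled without uniqueness enforcement).
  Whether features should be scaled before the distance computation is not
  fixed by convention; the default reuses the PCA scaling and is
  flag-controlled. Meat and sausage are analysed separately, with Bonferroni
  over the 4 or 5 subcategories tested.

The rank test and the PERMANOVA are implemented from their defining
computations inside the package; `stats::wilcox.test` and `vegan::adonis2`
serve as independent cross-checks in the test suite, never as the
implementation.

## The synthetic cohort generator

The generator exists so that every downstream stage is exercisable without
the survey's (external) product table. Its defaults *are* the published
study conditions: 18 (subcategory × arm) cells with the printed product
counts and nutrient means/SDs — 592 products in total. One documented unit
decision: the summary table's energy column is headed kJ but its values only
reconcile with the in-text kJ/kcal pairs as kcal (e.g. plant salami 272.50
printed vs "1142 kJ/100 g or 273 kcal/100 g"), so the configuration stores
kcal and derives kJ.

Marginals are normals truncated at zero — the summary table provides only
means and SDs, so anything richer (a copula, real inter-nutrient
correlation) would be invented. Two numerical choices matter:

* **Mean calibration.** A normal truncated at 0 has a mean above its
  location parameter; for small-mean cells (animal-arm fibre, 0.05 ± 0.16)
  the upward bias would approach one SD and the configured means would be
  unrecoverable. The generator therefore solves (Mills-ratio identity,
  `uniroot`) for the location that makes the *truncated* mean equal the
  configured mean.
* **Ordering constraints without bias.** Saturated fat ≤ fat and sugar ≤
  carbohydrate are enforced by drawing the dependent quantity from the
  interval [0, partner] by inverse CDF, again with the location calibrated so
  the average conditional mean over the drawn partner values equals the
  configured mean. Naive redraw-until-valid sampling would bias sugar
  downward by up to half an SD in the animal sausage cells, where mean sugar
  sits close to mean carbohydrate. When a configured mean is not attainable
  under the drawn partners the draw saturates toward the partner; a
  degenerate infeasible cell (zero SD) raises an error naming the cell.

Plant-arm ingredient lists are synthesised from a protein-source palette at
the survey's main-source frequencies (soy 36%, pea 33%, wheat 26%, sunflower
5%, faba bean 1%), a 40% chance of a secondary source drawn from the
remaining palette, and a 5% chance of added potato protein — chosen so the
implied share of good protein quality lands near the reported ~60%. Label
extras use the reported prevalences where printed (methylcellulose 59%,
flavourings 92%, fortification 12% with B12 0.38–1.3 µg and iron 2.1–5.3 mg)
and field-plausible rates where not (colouring vs plain paprika extract
20%/10%, gum thickener 35%, acid regulator 35%, preservative 10%). Animal-arm
products carry empty ingredient lists, mirroring the reference data sources,
which mostly lack them. Values are rounded to label precision (2 decimals; kJ
to 1). Seeds are explicit arguments everywhere; the generator saves and
restores the global RNG state.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: inter-nutrient correlations beyond the two ordering
constraints (real fat and energy correlate strongly; synthetic PERMANOVA
\(R^2\) in the meat categories accordingly runs higher than the survey's),
per-subcategory differences in protein-source mix (the survey found meat
analogues ahead of sausage analogues in protein quality; the synthetic
palette is uniform across subcategories), brand structure, price, regional
availability, and the exact additive inventory. Dataset-level magnitudes of
the survey (its Nutri-Score distribution percentages, 61% good protein
quality, PCA variance shares of 62.1%/75.9%, per-subcategory PERMANOVA
\(R^2/F\)) are therefore benchmark targets only against the authors'
downloadable dataset; at desk scale the package verifies the algorithmic
pieces exactly and the cohort-level effects directionally (plant sausage
subcategories score lower FSAm-NPS than their references on every seed
tried).

## Problem sizes and numerical conventions

The test suite runs the full 592-product default cohort (parameter recovery
over ten seeds, each cell mean within four standard errors with zero
constraint violations), exhaustive oracles at small n (all Mann–Whitney
labelings for pooled sizes ≤ 8–10; all 20 assignments of the 6-point
PERMANOVA toy against 9,999 sampled permutations), and 99–999 permutations
for pipeline-level checks; sums of squares must decompose to 1e−9.
Tie-breaking is by midranks everywhere; all tests are two-sided; Bonferroni
caps at 1. Score thresholds are strict inequalities, and the grade
boundaries fall at 0, 2, 10, 18. CSV round-trips are exact: upper-bound
values are re-emitted as `"<x"` and imputed fibre as an empty cell, which
re-imputes to the identical value on re-read.

## Limitations

Everything rests on declared label data: no bioavailability, digestibility,
fatty-acid composition or processing-level (NOVA/SIGA) assessment; protein
quality is a source-level heuristic, not an amino-acid computation; the
beverage/cheese/fats Nutri-Score scales are out of scope; and the additive
lexicon, while a superset of the survey's named examples, is not its verbatim
appendix list.
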