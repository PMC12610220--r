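# Nutrient panel: per-100 g declared quantities and quantities derived from
# them. Panels live as columns of the products data frame (see
# read_products_csv); the functions here are vectorised over those columns.

# EU Reg 1169/2011 energy conversion factors, kJ per g.
ENERGY_FACTORS <- c(fat = 37, cho = 17, protein = 17, fibre = 8)

NUTRIENT_COLS <- c("energy_kj", "energy_kcal", "fat_g", "satfat_g", "cho_g",
                   "sugar_g", "fibre_g", "protein_g", "salt_g")

#' Estimate missing fibre from the label's energy difference
#'
#' Fibre declaration is voluntary on EU labels. When it is missing, the
#' difference between declared energy and the energy accounted for by fat,
#' carbohydrate and protein can be attributed to fibre using the statutory
#' conversion factors (kJ/g: fat 37, carbohydrate 17, protein 17, fibre 8):
#' \deqn{fibre = max(0, (E_{kJ} - 37 f - 17 c - 17 p) / 8)}
#' The estimate is flagged unreliable when the raw residual is negative or
#' when it implies more fibre than carbohydrate + 2 g, either of which signals
#' an inconsistent declaration rather than true fibre.
#'
#' @param energy_kj declared energy, kJ/100 g.
#' @param fat_g,cho_g,protein_g declared macronutrients, g/100 g.
#' @return list with \code{fibre_g} (clamped at 0) and \code{reliable}
#'   (logical), both vectorised.
#' @examples
#' estimate_fibre_from_energy(500, 5, 10, 5)  # 7.5 g, reliable
#' @export
estimate_fibre_from_energy <- function(energy_kj, fat_g, cho_g, protein_g) {
  if (any(is.na(energy_kj) | is.na(fat_g) | is.na(cho_g) | is.na(protein_g))) {
    stop_lp("cannot impute fibre: energy, fat, carbohydrate and protein must all be present")
  }
  raw <- (energy_kj - ENERGY_FACTORS[["fat"]] * fat_g -
            ENERGY_FACTORS[["cho"]] * cho_g -
            ENERGY_FACTORS[["protein"]] * protein_g) / ENERGY_FACTORS[["fibre"]]
  fibre <- pmax(0, raw)
  reliable <- raw >= 0 & fibre <= cho_g + 2
  list(fibre_g = fibre, reliable = reliable)
}

#' Percentage of energy derived from protein
#'
#' Protein contributes 17 kJ per gram, so the share of a food's energy that
#' comes from protein is \code{100 * 17 * protein_g / energy_kj}.
#'
#' @param protein_g protein, g/100 g.
#' @param energy_kj declared energy, kJ/100 g; must be positive.
#' @return percentage (0-100 for physically consistent declarations).
#' @examples
#' protein_energy_percent(20.86, kj_from_kcal(272.50))  # about 31
#' @export
protein_energy_percent <- function(protein_g, energy_kj) {
  if (any(is.na(energy_kj)) || any(energy_kj <= 0)) {
    stop_lp("protein_energy_percent() requires energy_kj > 0")
  }
  100 * ENERGY_FACTORS[["protein"]] * protein_g / energy_kj
}

#' EU "source of protein" claim eligibility
#'
#' Under EU claim rules a food may carry a protein claim when at least 12% of
#' its energy value comes from protein. The boundary is inclusive.
#'
#' @inheritParams protein_energy_percent
#' @return logical vector.
#' @export
protein_claim_eligible <- function(protein_g, energy_kj) {
  protein_energy_percent(protein_g, energy_kj) >= 12
}

#' Share of the daily fibre recommendation covered by a 100 g portion
#'
#' @param fibre_g fibre, g/100 g.
#' @param reference_g daily reference intake in grams; defaults to the 30 g
#'   adult recommendation used by the German Nutrition Society.
#' @return percentage.
#' @export
fibre_daily_coverage <- function(fibre_g, reference_g = 30) {
  if (any(!is.na(fibre_g) & fibre_g < 0)) stop_lp("fibre must be non-negative")
  if (reference_g <= 0) stop_lp("reference intake must be positive")
  100 * fibre_g / reference_g
}
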