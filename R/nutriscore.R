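# 2023 FSAm-NPS point algorithm (general-foods scale) and Nutri-Score grades.
# The threshold tables are a versioned data structure so that a future
# algorithm revision is a data change, not a code change.

#' FSAm-NPS threshold tables (2023 general-foods scale)
#'
#' Point thresholds for the 2023 main-algorithm Nutri-Score. A component earns
#' one point per threshold strictly exceeded (\code{value > t}); the
#' fruits/vegetables/legumes (FVL) component maps >40% to 1, >60% to 2 and
#' >80% to 5 points. Unfavourable components: energy (0-10 points), saturated
#' fat (0-10), sugars (0-15), salt (0-20); favourable: protein (0-7), fibre
#' (0-5), FVL (0/1/2/5).
#'
#' @return named list of numeric threshold vectors plus a \code{version}
#'   string and the FVL point mapping.
#' @export
nutri_thresholds <- function() {
  list(
    version = "2023-main-foods",
    energy_kj = seq(335, 3350, by = 335),
    satfat_g = 1:10,
    sugars_g = c(3.4, 6.8, 10, 14, 17, 20, 24, 27, 31, 34, 37, 41, 44, 48, 51),
    salt_g = seq(0.2, 4.0, by = 0.2),
    protein_g = c(2.4, 4.8, 7.2, 9.6, 12, 14, 17),
    fibre_g = c(3.0, 4.1, 5.2, 6.3, 7.4),
    fvl_percent = c(40, 60, 80),
    fvl_points = c(1, 2, 5)
  )
}

#' Export / import the threshold tables as JSON
#'
#' @param thresholds a threshold list as returned by
#'   \code{\link{nutri_thresholds}}.
#' @param path JSON file path.
#' @export
thresholds_to_json <- function(thresholds = nutri_thresholds(), path) {
  jsonlite::write_json(thresholds, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname thresholds_to_json
#' @export
thresholds_from_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Points for a single FSAm-NPS component
#'
#' @param nutrient one of \code{"energy_kj"}, \code{"satfat_g"},
#'   \code{"sugars_g"}, \code{"salt_g"}, \code{"protein_g"}, \code{"fibre_g"},
#'   \code{"fvl_percent"}.
#' @param value non-negative quantity (kJ/100 g, g/100 g, or percent).
#' @param thresholds threshold tables, default \code{\link{nutri_thresholds}}.
#' @return integer points; a monotone non-decreasing step function of
#'   \code{value} with strict thresholds.
#' @examples
#' component_points("salt_g", 4.2)     # 20, the component maximum
#' component_points("protein_g", 18)   # 7
#' @export
component_points <- function(nutrient, value, thresholds = nutri_thresholds()) {
  if (any(!is.na(value) & value < 0)) stop_lp("component value must be non-negative")
  if (nutrient == "fvl_percent") {
    pts <- integer(length(value))
    for (k in seq_along(thresholds$fvl_percent)) {
      pts[value > thresholds$fvl_percent[k]] <- thresholds$fvl_points[k]
    }
    return(pts)
  }
  t <- thresholds[[nutrient]]
  if (is.null(t) || !is.numeric(t)) stop_lp("unknown nutrient '%s'", nutrient)
  vapply(value, function(v) sum(v > t), numeric(1))
}

#' Compute the FSAm-NPS score and Nutri-Score grade
#'
#' Implements the 2023 general-foods algorithm with the survey's adaptations:
#' \itemize{
#'   \item Unfavourable points N = energy + saturated fat + sugars + salt
#'     points (0-55); favourable points P = protein + fibre + FVL (0-17);
#'     total = N - P, giving the algorithm range -17 to +55.
#'   \item Protein points count only when N < 11 or the FVL component is at
#'     its 5-point maximum.
#'   \item For red meat and products derived from it
#'     (\code{red_meat_derived}), counted protein points are capped at 2.
#'   \item For products customarily salted during preparation
#'     (\code{salt_added_in_prep}, e.g. minced meat), 0.5 g/100 g is added to
#'     the declared salt before scoring.
#'   \item The FVL percentage is an implemented component, but the pipeline
#'     passes 0 for all products: protein-isolate analogues contain no
#'     minimally processed fruit/vegetable/legume fraction and the component
#'     only scores above 40%.
#' }
#'
#' @param panel data.frame (or list) with columns \code{energy_kj},
#'   \code{satfat_g}, \code{sugar_g}, \code{salt_g}, \code{protein_g},
#'   \code{fibre_g}; all vectorised.
#' @param red_meat_derived logical, protein-point cap applies.
#' @param salt_added_in_prep logical, add 0.5 g salt before scoring.
#' @param fvl_percent fruits/vegetables/legumes percentage in [0, 100].
#' @param thresholds threshold tables.
#' @return data.frame of class \code{fsam_nps}: per-component points, the
#'   unfavourable sum \code{n_unfavourable}, favourable sum
#'   \code{p_favourable}, flags \code{protein_counted}, \code{protein_capped},
#'   \code{salt_adjustment_applied}, the \code{total_score} and \code{grade}.
#' @examples
#' compute_fsam_nps(list(energy_kj = 3360, satfat_g = 11, sugar_g = 52,
#'                       salt_g = 4.2, protein_g = 0, fibre_g = 0))  # score 55
#' @export
compute_fsam_nps <- function(panel, red_meat_derived = FALSE,
                             salt_added_in_prep = FALSE, fvl_percent = 0,
                             thresholds = nutri_thresholds()) {
  need <- c("energy_kj", "satfat_g", "sugar_g", "salt_g", "protein_g", "fibre_g")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols) > 0) {
    stop_lp("panel lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (any(fvl_percent < 0 | fvl_percent > 100)) {
    stop_lp("fvl_percent must lie in [0, 100]")
  }
  n <- length(panel$energy_kj)
  red_meat_derived <- rep_len(red_meat_derived, n)
  salt_added_in_prep <- rep_len(salt_added_in_prep, n)
  fvl_percent <- rep_len(fvl_percent, n)

  salt_scored <- panel$salt_g + ifelse(salt_added_in_prep, 0.5, 0)
  energy_pts <- component_points("energy_kj", panel$energy_kj, thresholds)
  satfat_pts <- component_points("satfat_g", panel$satfat_g, thresholds)
  sugars_pts <- component_points("sugars_g", panel$sugar_g, thresholds)
  salt_pts <- component_points("salt_g", salt_scored, thresholds)
  protein_pts <- component_points("protein_g", panel$protein_g, thresholds)
  fibre_pts <- component_points("fibre_g", panel$fibre_g, thresholds)
  fvl_pts <- component_points("fvl_percent", fvl_percent, thresholds)

  N <- energy_pts + satfat_pts + sugars_pts + salt_pts
  counted <- N < 11 | fvl_pts == 5
  capped <- counted & red_meat_derived & protein_pts > 2
  protein_final <- ifelse(counted,
                          ifelse(red_meat_derived, pmin(protein_pts, 2),
                                 protein_pts),
                          0)
  P <- protein_final + fibre_pts + fvl_pts
  total <- as.integer(N - P)
  out <- data.frame(
    energy_pts = as.integer(energy_pts),
    satfat_pts = as.integer(satfat_pts),
    sugars_pts = as.integer(sugars_pts),
    salt_pts = as.integer(salt_pts),
    protein_pts = as.integer(protein_pts),
    fibre_pts = as.integer(fibre_pts),
    fvl_pts = as.integer(fvl_pts),
    n_unfavourable = as.integer(N),
    p_favourable = as.integer(P),
    protein_counted = counted,
    protein_capped = capped,
    salt_adjustment_applied = salt_added_in_prep,
    total_score = total,
    grade = grade_from_score(total)
  )
  class(out) <- c("fsam_nps", "data.frame")
  out
}

#' Map an FSAm-NPS score to a Nutri-Score grade
#'
#' 2023 food-scale grade thresholds: A for scores of 0 or less, B for 1-2,
#' C for 3-10, D for 11-18, E for 19 and above.
#'
#' @param score integer score(s) in [-17, 55].
#' @return character vector of grades "A".."E".
#' @export
grade_from_score <- function(score) {
  if (any(score < -17 | score > 55)) {
    stop_lp("FSAm-NPS score out of range [-17, 55]")
  }
  cut(score, breaks = c(-Inf, 0, 2, 10, 18, Inf),
      labels = c("A", "B", "C", "D", "E"), right = TRUE) |> as.character()
}

#' Observed extrema of the scoring algorithm
#'
#' Exhaustively evaluates \code{\link{compute_fsam_nps}} over the Cartesian
#' product of per-component extreme inputs (each component at a zero-point
#' value and at a maximum-point value, 2^7 = 128 combinations, FVL included)
#' and returns the observed minimum and maximum total score.
#'
#' @return integer vector \code{c(min, max)}; equals \code{c(-17, 55)} for
#'   the 2023 tables.
#' @export
score_bounds <- function() {
  grid <- expand.grid(
    energy_kj = c(0, 3360), satfat_g = c(0, 11), sugar_g = c(0, 52),
    salt_g = c(0, 4.2), protein_g = c(0, 18), fibre_g = c(0, 8),
    fvl = c(0, 85)
  )
  scores <- compute_fsam_nps(grid, fvl_percent = grid$fvl)$total_score
  c(min(scores), max(scores))
}

#' Score every product of a cohort
#'
#' Applies \code{\link{compute_fsam_nps}} to each product using its panel and
#' modifier flags, with the FVL percentage fixed at 0 (see
#' \code{compute_fsam_nps}). Imputed fibre is used for scoring (0 is its
#' floor); provenance is carried along in \code{fibre_status}.
#'
#' @param products validated products data.frame.
#' @return data.frame: product identity columns plus the
#'   \code{\link{compute_fsam_nps}} breakdown.
#' @export
score_products <- function(products) {
  br <- compute_fsam_nps(products,
                         red_meat_derived = products$red_meat_derived,
                         salt_added_in_prep = products$salt_added_in_prep,
                         fvl_percent = 0)
  cbind(products[c("product_id", "arm", "main_category", "subcategory")],
        fibre_status = products$fibre_status %||% "declared", br)
}
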