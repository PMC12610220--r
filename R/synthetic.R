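# Seeded synthetic cohort generator. Marginals are truncated normals whose
# location is calibrated so the realized (truncated) mean equals the
# configured mean; logical constraints (satfat <= fat, sugar <= cho) are
# enforced by sampling the dependent quantity from the interval [0, partner]
# with the same mean calibration, so constraint enforcement does not bias
# the recovered cell means.

NUTRIENT_KEYS <- c("energy_kcal", "fat", "satfat", "cho", "sugar", "fibre",
                   "protein", "salt")

# One row per (subcategory, arm) cell; columns mean_*/sd_* on the kcal/g
# scale. The reference survey's printed energy column is on the kcal scale
# (its in-text cross-checks, e.g. 1142 kJ = 273 kcal for plant salami mean
# 272.50, only reconcile as kcal), so defaults store kcal and derive kJ.
.table2_cells <- function() {
  # subcategory, arm, n, then mean,sd pairs for the 8 nutrients
  rows <- list(
    list("minced_meat", "plant", 52, 205.83, 45.01, 12.41, 4.64, 3.51, 3.35, 6.40, 3.18, 1.50, 0.87, 4.93, 2.10, 14.64, 3.97, 1.61, 0.47),
    list("minced_meat", "animal", 30, 245.73, 39.59, 18.02, 4.46, 7.53, 2.05, 3.18, 3.84, 0.56, 0.60, 0.16, 0.28, 17.86, 3.47, 1.18, 0.45),
    list("chicken", "plant", 43, 177.37, 63.56, 9.04, 6.66, 0.91, 0.66, 4.12, 2.21, 0.94, 0.87, 4.89, 1.52, 17.42, 5.46, 1.54, 0.45),
    list("chicken", "animal", 27, 148.67, 42.36, 6.94, 5.10, 2.06, 1.76, 1.00, 1.44, 0.51, 0.62, 0.05, 0.12, 20.56, 2.82, 1.24, 0.76),
    list("breaded_meat", "plant", 55, 249.58, 40.53, 13.01, 3.73, 1.37, 0.66, 18.33, 3.81, 1.06, 0.64, 4.52, 1.50, 12.49, 2.37, 1.35, 0.31),
    list("breaded_meat", "animal", 29, 229.66, 37.24, 10.80, 3.72, 2.83, 2.04, 16.00, 4.29, 0.90, 0.34, 0.77, 0.54, 16.66, 2.99, 1.07, 0.49),
    list("red_meat", "plant", 32, 170.63, 60.82, 8.32, 6.21, 1.25, 1.65, 5.73, 3.93, 2.45, 2.41, 4.90, 1.73, 15.44, 5.41, 1.77, 0.47),
    list("red_meat", "animal", 15, 155.27, 27.12, 7.37, 3.18, 2.81, 1.24, 0.82, 0.81, 0.48, 0.43, 0.12, 0.16, 21.28, 4.01, 0.86, 0.35),
    list("bratwurst", "plant", 22, 196.05, 37.62, 13.49, 3.64, 2.30, 1.89, 5.69, 2.51, 1.38, 1.19, 3.75, 2.20, 11.24, 6.37, 1.95, 0.49),
    list("bratwurst", "animal", 26, 284.23, 42.79, 24.66, 5.20, 10.14, 2.33, 0.59, 0.38, 0.44, 0.30, 0.07, 0.19, 15.27, 2.93, 1.97, 0.39),
    list("cooked_sausage", "plant", 47, 150.43, 43.72, 12.02, 4.33, 0.94, 0.36, 3.33, 1.47, 1.27, 0.88, 5.06, 2.11, 4.64, 2.34, 2.13, 0.36),
    list("cooked_sausage", "animal", 48, 249.58, 46.07, 21.55, 5.68, 7.98, 2.63, 0.85, 0.73, 0.61, 0.61, 0.13, 0.20, 13.19, 1.63, 2.10, 0.27),
    list("salami", "plant", 24, 272.50, 81.01, 15.98, 7.06, 4.26, 4.48, 9.33, 3.65, 3.70, 1.79, 4.15, 2.53, 20.86, 11.24, 2.72, 0.54),
    list("salami", "animal", 67, 378.27, 76.45, 31.07, 7.48, 12.64, 3.06, 0.86, 0.82, 0.72, 0.67, 0.09, 0.21, 23.99, 4.28, 3.77, 0.68),
    list("ham_bacon", "plant", 11, 167.82, 84.19, 5.87, 5.70, 0.85, 0.58, 7.22, 3.83, 3.21, 1.93, 3.88, 1.76, 19.64, 12.72, 2.60, 0.37),
    list("ham_bacon", "animal", 19, 202.63, 89.03, 12.88, 11.12, 5.15, 4.52, 0.65, 0.55, 0.62, 0.54, 0.05, 0.16, 21.03, 5.19, 3.07, 1.50),
    list("spreadable_sausage", "plant", 12, 224.83, 89.99, 18.38, 9.38, 3.87, 4.67, 7.26, 2.08, 1.18, 0.79, 3.84, 2.14, 5.67, 1.59, 1.93, 0.38),
    list("spreadable_sausage", "animal", 33, 348.79, 74.79, 32.19, 9.22, 12.91, 3.71, 1.15, 0.80, 0.81, 0.71, 0.28, 0.97, 13.93, 2.41, 2.08, 0.57)
  )
  cells <- data.frame(
    subcategory = vapply(rows, function(r) r[[1]], character(1)),
    arm = vapply(rows, function(r) r[[2]], character(1)),
    n = vapply(rows, function(r) r[[3]], numeric(1)),
    stringsAsFactors = FALSE
  )
  tab <- subcategory_table()
  cells$main_category <- tab$main_category[match(cells$subcategory,
                                                 tab$subcategory)]
  for (k in seq_along(NUTRIENT_KEYS)) {
    cells[[paste0("mean_", NUTRIENT_KEYS[k])]] <-
      vapply(rows, function(r) r[[2 + 2 * k]], numeric(1))
    cells[[paste0("sd_", NUTRIENT_KEYS[k])]] <-
      vapply(rows, function(r) r[[3 + 2 * k]], numeric(1))
  }
  cells[c("subcategory", "main_category", "arm", "n",
          as.vector(rbind(paste0("mean_", NUTRIENT_KEYS),
                          paste0("sd_", NUTRIENT_KEYS))))]
}

#' Default synthetic-cohort configuration
#'
#' Returns the full 9-subcategory x 2-arm configuration (18 cells, 592
#' products) whose per-cell product counts and nutrient means/SDs reproduce
#' the reference survey's summary table verbatim, together with the
#' ingredient-synthesis parameters for the plant arm: the protein-source
#' palette (soy 36%, pea 33%, wheat 26%, sunflower 5%, faba bean 1%), the
#' probability of a secondary protein source, and prevalence rates for
#' methylcellulose, flavourings, paprika-extract variants, potato protein and
#' micronutrient fortification. The kebab-style niche has no animal reference
#' on the market and is represented only through the red-meat subcategory, so
#' the default keeps the nine paired rows.
#'
#' @return object of class \code{cohort_config}: a list with elements
#'   \code{cells} (data.frame of per-cell counts/means/SDs),
#'   \code{palette} (protein-source frequencies), scalar prevalence
#'   parameters, and \code{constraint_tolerance}.
#' @export
default_config_from_table2 <- function() {
  structure(list(
    cells = .table2_cells(),
    palette = data.frame(
      source = c("soy", "pea", "wheat", "sunflower", "faba_bean"),
      frequency = c(0.36, 0.33, 0.26, 0.05, 0.01),
      stringsAsFactors = FALSE
    ),
    secondary_source_prob = 0.40,
    potato_protein_prob = 0.05,
    methylcellulose_prob = 0.59,
    flavouring_prob = 0.92,
    colouring_paprika_prob = 0.20,
    plain_paprika_prob = 0.10,
    thickener_gum_prob = 0.35,
    acid_regulator_prob = 0.35,
    preservative_prob = 0.10,
    fortified_prob = 0.12,
    constraint_tolerance = 0.02
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration:",
      nrow(x$cells), "cells,", sum(x$cells$n), "products\n")
  cat("Protein palette:",
      paste(sprintf("%s %.0f%%", x$palette$source, 100 * x$palette$frequency),
            collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a cohort configuration to/from JSON
#'
#' @param config a \code{cohort_config} object.
#' @param path JSON file path.
#' @export
config_to_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$cells <- as.data.frame(x$cells)
  x$palette <- as.data.frame(x$palette)
  structure(x, class = "cohort_config")
}

# Location parameter mu such that a normal(mu, sd) truncated below at 0 has
# mean `target`. Uses the Mills-ratio identity E[X | X>0] = mu + sd*lambda
# with lambda = phi(-mu/sd)/Phi(mu/sd), solved by uniroot. For targets many
# SDs above zero the truncation is immaterial and mu = target.
.tnorm_location <- function(target, sd) {
  if (sd <= 0) return(target)
  if (target <= 0) stop_lp("truncated-normal target mean must be positive")
  if (stats::pnorm(0, target, sd) < 1e-12) return(target)
  f <- function(mu) {
    a <- -mu / sd
    lambda <- exp(stats::dnorm(a, log = TRUE) -
                    stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
    mu + sd * lambda - target
  }
  stats::uniroot(f, lower = target - 20 * sd, upper = target + sd,
                 tol = 1e-12)$root
}

# Draw n values from the mean-calibrated truncated normal via inverse CDF.
.r_tnorm <- function(n, target, sd) {
  if (sd <= 0 || target <= 0) return(rep(max(target, 0), n))
  mu <- .tnorm_location(target, sd)
  lo <- stats::pnorm(0, mu, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean = mu, sd = sd)
}

# Mean of a normal(mu, sd) truncated to [lo, hi].
.etnorm <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  if (z < 1e-12) return(if (mu > hi) hi else lo)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Draw the dependent quantity of an ordering constraint (satfat <= fat,
# sugar <= cho): each value is sampled exactly from a normal truncated to
# [0, partner_i] by inverse CDF, with a shared location parameter calibrated
# so that the average conditional mean over the partner draws equals the
# configured cell mean. When the target mean is not attainable (it exceeds
# what the partner values allow), the draw saturates towards the partner and
# the residual shortfall is the partner's own sampling fluctuation; a
# degenerate (zero-SD) infeasible cell is an error naming the cell.
.draw_constrained <- function(n, target, sd, partner, cell_id) {
  if (sd <= 0 || target <= 0) {
    x <- rep(max(target, 0), n)
    if (any(x > partner)) {
      stop_lp("infeasible ordering constraint in cell %s (constant %.3g exceeds partner)",
              cell_id, target)
    }
    return(x)
  }
  mean_of <- function(mu) {
    mean(vapply(partner, function(b) .etnorm(mu, sd, 0, b), numeric(1)))
  }
  lower <- target - 20 * sd
  upper <- max(partner) + 20 * sd
  mu <- if (mean_of(upper) <= target) upper
        else stats::uniroot(function(m) mean_of(m) - target,
                            lower = lower, upper = upper, tol = 1e-10)$root
  plo <- stats::pnorm(0, mu, sd)
  phi <- stats::pnorm(partner, mu, sd)
  u <- stats::runif(n, plo, phi)
  x <- stats::qnorm(u, mean = mu, sd = sd)
  pmin(pmax(x, 0), partner)
}

.synth_ingredients <- function(n, config) {
  pal <- config$palette
  source_name <- c(soy = "soy protein concentrate",
                   pea = "pea protein isolate",
                   wheat = "wheat gluten",
                   sunflower = "sunflower protein",
                   faba_bean = "faba bean protein",
                   potato = "potato protein")
  main <- sample(pal$source, n, replace = TRUE, prob = pal$frequency)
  has_second <- stats::runif(n) < config$secondary_source_prob
  second <- rep(NA_character_, n)
  for (i in which(has_second)) {
    others <- pal$source[pal$source != main[i]]
    w <- pal$frequency[pal$source != main[i]]
    second[i] <- sample(others, 1, prob = w)
  }
  has_potato <- stats::runif(n) < config$potato_protein_prob
  has_mc <- stats::runif(n) < config$methylcellulose_prob
  u_pap <- stats::runif(n)
  pap <- ifelse(u_pap < config$colouring_paprika_prob, "colouring paprika extract",
                ifelse(u_pap < config$colouring_paprika_prob +
                         config$plain_paprika_prob, "paprika extract", NA))
  has_gum <- stats::runif(n) < (config$thickener_gum_prob %||% 0)
  has_acid <- stats::runif(n) < (config$acid_regulator_prob %||% 0)
  has_pres <- stats::runif(n) < (config$preservative_prob %||% 0)
  has_flav <- stats::runif(n) < config$flavouring_prob
  texts <- character(n)
  for (i in seq_len(n)) {
    parts <- c("water", source_name[[main[i]]],
               if (!is.na(second[i])) source_name[[second[i]]],
               if (has_potato[i]) source_name[["potato"]],
               "rapeseed oil",
               if (has_mc[i]) "methylcellulose",
               if (has_gum[i]) "xanthan gum",
               if (has_acid[i]) "citric acid",
               if (has_pres[i]) "potassium sorbate",
               "salt", "spices",
               if (!is.na(pap[i])) pap[i],
               if (has_flav[i]) "natural flavouring")
    texts[i] <- paste(parts, collapse = ", ")
  }
  texts
}

.synth_fortificants <- function(n, config) {
  fortified <- stats::runif(n) < config$fortified_prob
  out <- character(n)
  b12 <- round(stats::runif(n, 0.38, 1.3), 2)
  iron <- round(stats::runif(n, 2.1, 5.3), 2)
  out[fortified] <- sprintf("vitamin_b12=%sug;iron=%smg",
                            format_num(b12[fortified]),
                            format_num(iron[fortified]))
  out
}

#' Generate a seeded synthetic product cohort
#'
#' For each (subcategory, arm) cell of the configuration, nutrient quantities
#' are drawn per 100 g from truncated-normal marginals calibrated to the
#' configured means/SDs; saturated fat and sugar are drawn conditionally on
#' not exceeding total fat and carbohydrate respectively, with the location
#' re-calibrated so the constraint does not bias the cell mean; energy in kJ
#' is derived
#' from the drawn kcal value with 4.184 kJ/kcal; values are rounded to label
#' precision (2 decimals, kJ to 1 decimal). Plant-arm ingredient lists are
#' synthesised from the configured protein-source palette together with
#' additive/flavouring/fortification prevalences; animal-arm products carry
#' empty ingredient lists, mirroring the reference data sources. Modifier
#' flags take the per-subcategory defaults. The output is deterministic given
#' \code{seed} and passes \code{\link{validate_products}}.
#'
#' @param config a \code{cohort_config}, e.g.
#'   \code{\link{default_config_from_table2}()}.
#' @param seed integer seed; the generator never touches the global RNG state.
#' @return products data.frame in the CSV schema of
#'   \code{\link{read_products_csv}}.
#' @export
generate_cohort <- function(config = default_config_from_table2(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  cells <- config$cells
  with_seed(seed, {
    parts <- vector("list", nrow(cells))
    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci, ]
      n <- cell$n
      cell_id <- paste(cell$subcategory, cell$arm, sep = "/")
      g <- function(key) cell[[paste0("mean_", key)]]
      s <- function(key) cell[[paste0("sd_", key)]]
      energy_kcal <- .r_tnorm(n, g("energy_kcal"), s("energy_kcal"))
      fat <- .r_tnorm(n, g("fat"), s("fat"))
      satfat <- .draw_constrained(n, g("satfat"), s("satfat"), fat, cell_id)
      cho <- .r_tnorm(n, g("cho"), s("cho"))
      sugar <- .draw_constrained(n, g("sugar"), s("sugar"), cho, cell_id)
      fibre <- .r_tnorm(n, g("fibre"), s("fibre"))
      protein <- .r_tnorm(n, g("protein"), s("protein"))
      salt <- .r_tnorm(n, g("salt"), s("salt"))
      energy_kcal <- round(energy_kcal, 2)
      flags <- default_modifier_flags(rep(cell$arm, n),
                                      rep(cell$subcategory, n))
      plant <- cell$arm == "plant"
      df <- data.frame(
        product_id = sprintf("%s_%s_%03d", substr(cell$arm, 1, 2),
                             cell$subcategory, seq_len(n)),
        name = sprintf("synthetic %s (%s) %d",
                       gsub("_", " ", cell$subcategory), cell$arm, seq_len(n)),
        brand = sprintf("brand_%02d", 1 + (seq_len(n) - 1L) %% 12L),
        arm = cell$arm,
        main_category = cell$main_category,
        subcategory = cell$subcategory,
        energy_kj = round(kj_from_kcal(energy_kcal), 1),
        energy_kcal = energy_kcal,
        fat_g = round(fat, 2),
        satfat_g = round(satfat, 2),
        cho_g = round(cho, 2),
        sugar_g = round(sugar, 2),
        fibre_g = round(fibre, 2),
        protein_g = round(protein, 2),
        salt_g = round(salt, 2),
        fibre_status = "declared",
        fibre_reliable = TRUE,
        upper_bound_nutrients = "",
        ingredients_text = if (plant) .synth_ingredients(n, config) else "",
        fortificants = if (plant) .synth_fortificants(n, config) else "",
        red_meat_derived = flags$red_meat_derived,
        salt_added_in_prep = flags$salt_added_in_prep,
        stringsAsFactors = FALSE
      )
      parts[[ci]] <- df
    }
    cohort <- do.call(rbind, parts)
    rownames(cohort) <- NULL
    validate_products(cohort)
    cohort
  })
}
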