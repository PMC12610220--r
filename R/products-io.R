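# Product records: categorisation scheme, validation, CSV I/O.

#' Product categorisation scheme
#'
#' Nine retail subcategories, four under the meat main category and five under
#' sausage. The per-subcategory defaults for the two Nutri-Score modifier
#' flags reflect the animal-arm product types: \code{red_meat_default_ab}
#' marks pork/beef-derived reference products (protein-point cap applies) and
#' \code{salt_added_default_ab} marks products customarily salted during
#' preparation (minced and red meat), for which 0.5 g/100 g salt is added
#' before scoring. Plant-arm products default to \code{FALSE} for both.
#'
#' @return data.frame with columns \code{subcategory}, \code{main_category},
#'   \code{label}, \code{red_meat_default_ab}, \code{salt_added_default_ab}.
#' @export
subcategory_table <- function() {
  data.frame(
    subcategory = c("minced_meat", "chicken", "breaded_meat", "red_meat",
                    "bratwurst", "cooked_sausage", "salami", "ham_bacon",
                    "spreadable_sausage"),
    main_category = c(rep("meat", 4), rep("sausage", 5)),
    label = c("Minced meat", "Chicken", "Breaded meat", "Red meat",
              "Bratwurst", "Cooked sausage", "Salami", "Ham/bacon",
              "Spreadable sausage"),
    red_meat_default_ab = c(TRUE, FALSE, FALSE, TRUE,
                            TRUE, TRUE, TRUE, TRUE, TRUE),
    salt_added_default_ab = c(TRUE, FALSE, FALSE, TRUE,
                              FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default Nutri-Score modifier flags for a product
#'
#' @param arm "plant" or "animal".
#' @param subcategory one of the nine subcategory identifiers.
#' @return list with logicals \code{red_meat_derived} and
#'   \code{salt_added_in_prep}. Vectorised over both arguments.
#' @export
default_modifier_flags <- function(arm, subcategory) {
  tab <- subcategory_table()
  idx <- match(subcategory, tab$subcategory)
  if (any(is.na(idx))) {
    stop_lp("unknown subcategory: %s",
            paste(unique(subcategory[is.na(idx)]), collapse = ", "))
  }
  animal <- arm == "animal"
  list(red_meat_derived = animal & tab$red_meat_default_ab[idx],
       salt_added_in_prep = animal & tab$salt_added_default_ab[idx])
}

PRODUCT_COLS <- c("product_id", "name", "brand", "arm", "main_category",
                  "subcategory", NUTRIENT_COLS, "ingredients_text",
                  "fortificants", "red_meat_derived", "salt_added_in_prep")

#' Validate a products table
#'
#' Checks the structural and nutritional invariants of a product table:
#' known arm/category/subcategory levels, subcategory consistent with its main
#' category, non-negative quantities, saturated fat not exceeding total fat,
#' sugar not exceeding carbohydrate, kJ/kcal agreement within \code{tol}
#' (kcal = kJ/4.184) where both are present, and the red-meat flag restricted
#' to animal-arm products of pork/beef-derived subcategories. Violations are
#' reported with row indices.
#'
#' @param products data.frame with the columns listed in
#'   \code{read_products_csv()}.
#' @param tol relative tolerance for kJ/kcal consistency (default 0.02).
#' @return the validated data.frame, invisibly.
#' @export
validate_products <- function(products, tol = 0.02) {
  missing_cols <- setdiff(PRODUCT_COLS, names(products))
  if (length(missing_cols) > 0) {
    stop_lp("products table lacks mandatory columns: %s",
            paste(missing_cols, collapse = ", "))
  }
  tab <- subcategory_table()
  problems <- character(0)
  add <- function(rows, what) {
    if (any(rows, na.rm = TRUE)) {
      problems <<- c(problems, sprintf(
        "rows %s: %s", paste(which(rows), collapse = ","), what))
    }
  }
  add(!products$arm %in% c("plant", "animal"), "invalid arm")
  add(!products$subcategory %in% tab$subcategory, "invalid subcategory")
  idx <- match(products$subcategory, tab$subcategory)
  ok_sub <- !is.na(idx)
  add(ok_sub & products$main_category != tab$main_category[idx],
      "subcategory inconsistent with main_category")
  for (col in setdiff(NUTRIENT_COLS, "fibre_g")) {
    add(is.na(products[[col]]), sprintf("missing %s", col))
  }
  for (col in NUTRIENT_COLS) {
    add(!is.na(products[[col]]) & products[[col]] < 0,
        sprintf("negative %s", col))
  }
  add(products$satfat_g > products$fat_g + 1e-9, "saturated fat exceeds fat")
  add(products$sugar_g > products$cho_g + 1e-9, "sugar exceeds carbohydrates")
  both <- !is.na(products$energy_kj) & !is.na(products$energy_kcal)
  dev <- abs(products$energy_kcal * 4.184 - products$energy_kj)
  add(both & dev > tol * pmax(products$energy_kj, 1),
      "energy_kj and energy_kcal inconsistent")
  rm_ok <- tab$red_meat_default_ab[idx]
  add(products$red_meat_derived &
        (products$arm != "animal" | (ok_sub & !rm_ok)),
      "red_meat_derived allowed only for animal-arm pork/beef subcategories")
  if (length(problems) > 0) {
    stop_lp("invalid products table:\n  %s", paste(problems, collapse = "\n  "))
  }
  invisible(products)
}

#' Read / write a products CSV
#'
#' The products CSV (UTF-8, header row) carries one product per row with
#' columns \code{product_id, name, brand, arm, main_category, subcategory,
#' energy_kj, energy_kcal, fat_g, satfat_g, cho_g, sugar_g, fibre_g,
#' protein_g, salt_g, ingredients_text, fortificants, red_meat_derived,
#' salt_added_in_prep}. Nutrient cells may use decimal commas and the
#' upper-bound notation \code{"<x"}; upper-bound declarations are recorded at
#' \code{x} and the affected nutrient names collected in the
#' \code{upper_bound_nutrients} column. A missing \code{energy_kj} or
#' \code{energy_kcal} is derived from the other. An empty \code{fibre_g}
#' triggers imputation from the energy difference (see
#' \code{\link{estimate_fibre_from_energy}}); \code{fibre_status} records
#' declared/imputed/missing provenance and \code{fibre_reliable} the
#' imputation reliability flag. Empty modifier-flag cells receive the
#' per-subcategory defaults of \code{\link{default_modifier_flags}}.
#'
#' \code{write_products_csv} inverts the reader: upper-bound values are
#' written back as \code{"<x"} and non-declared fibre as an empty cell (so a
#' written file re-imputes to the identical value), making
#' write-then-read an identity on all fields.
#'
#' @param path CSV file path.
#' @param impute_fibre impute missing fibre on read (default TRUE).
#' @return \code{read_products_csv}: validated products data.frame.
#' @export
read_products_csv <- function(path, impute_fibre = TRUE) {
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8", check.names = FALSE)
  missing_cols <- setdiff(PRODUCT_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop_lp("CSV lacks mandatory columns: %s",
            paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  out <- raw[c("product_id", "name", "brand", "arm", "main_category",
               "subcategory")]
  ub <- character(n)
  for (col in NUTRIENT_COLS) {
    p <- parse_label_values(raw[[col]])
    out[[col]] <- p$value
    flagged <- p$upper_bound
    ub <- ifelse(flagged, ifelse(nzchar(ub), paste(ub, col, sep = ";"), col), ub)
  }
  # fill whichever energy unit is absent from the other
  kj_na <- is.na(out$energy_kj)
  kcal_na <- is.na(out$energy_kcal)
  out$energy_kj[kj_na] <- kj_from_kcal(out$energy_kcal[kj_na])
  out$energy_kcal[kcal_na & !kj_na] <- kcal_from_kj(out$energy_kj[kcal_na & !kj_na])

  out$fibre_status <- ifelse(is.na(out$fibre_g), "missing", "declared")
  out$fibre_reliable <- !is.na(out$fibre_g)
  if (impute_fibre && any(out$fibre_status == "missing")) {
    i <- out$fibre_status == "missing"
    imp <- estimate_fibre_from_energy(out$energy_kj[i], out$fat_g[i],
                                      out$cho_g[i], out$protein_g[i])
    out$fibre_g[i] <- imp$fibre_g
    out$fibre_reliable[i] <- imp$reliable
    out$fibre_status[i] <- "imputed"
  }
  out$upper_bound_nutrients <- ub
  out$ingredients_text <- raw$ingredients_text
  out$fortificants <- raw$fortificants
  defaults <- default_modifier_flags(out$arm, out$subcategory)
  parse_flag <- function(x, default) {
    x <- tolower(trimws(x))
    ifelse(nzchar(x), x %in% c("true", "t", "1", "yes"), default)
  }
  out$red_meat_derived <- parse_flag(raw$red_meat_derived,
                                     defaults$red_meat_derived)
  out$salt_added_in_prep <- parse_flag(raw$salt_added_in_prep,
                                       defaults$salt_added_in_prep)
  validate_products(out)
  out
}

#' @rdname read_products_csv
#' @param products validated products data.frame.
#' @export
write_products_csv <- function(products, path) {
  validate_products(products)
  n <- nrow(products)
  out <- products[c("product_id", "name", "brand", "arm", "main_category",
                    "subcategory")]
  ub_lists <- strsplit(products$upper_bound_nutrients %||% character(n), ";",
                       fixed = TRUE)
  status <- products$fibre_status %||% rep("declared", n)
  for (col in NUTRIENT_COLS) {
    vals <- format_num(products[[col]])
    if (col == "fibre_g") vals[status != "declared"] <- ""
    flagged <- vapply(ub_lists, function(u) col %in% u, logical(1))
    vals[flagged & nzchar(vals)] <- paste0("<", vals[flagged & nzchar(vals)])
    out[[col]] <- vals
  }
  out$ingredients_text <- products$ingredients_text
  out$fortificants <- products$fortificants
  out$red_meat_derived <- tolower(as.character(products$red_meat_derived))
  out$salt_added_in_prep <- tolower(as.character(products$salt_added_in_prep))
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}
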