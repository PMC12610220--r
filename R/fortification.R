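# Micronutrient fortification (NRV coverage) and additive/flavouring
# annotation of ingredient lists.

#' Nutrient reference value (NRV) table
#'
#' EU daily reference values used for label %-coverage; vitamin B12 carries
#' the 4.0 µg NRV. Units are µg for B12/vitamin D/iodine and mg otherwise.
#'
#' @param path JSON file; defaults to the table shipped with the package.
#' @return data.frame with columns \code{nutrient}, \code{nrv}, \code{unit}.
#' @export
default_nrv_table <- function(path = system.file("extdata", "nrv_table.json",
                                                 package = "labelprofiler")) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(x$entries)
}

#' Percent of the daily reference value covered by 100 g
#'
#' Linear in amount: \code{100 * amount / NRV}; amounts are interpreted in
#' the nutrient's NRV unit (µg for vitamin B12).
#'
#' @param nutrient nutrient identifier present in the NRV table.
#' @param amount amount per 100 g, same unit as the table entry.
#' @param nrv_table NRV table.
#' @return percentage.
#' @examples
#' nrv_coverage("vitamin_b12", 1.3)   # 32.5
#' @export
nrv_coverage <- function(nutrient, amount, nrv_table = default_nrv_table()) {
  idx <- match(nutrient, nrv_table$nutrient)
  if (any(is.na(idx))) {
    stop_lp("no NRV entry for nutrient(s): %s",
            paste(unique(nutrient[is.na(idx)]), collapse = ", "))
  }
  if (any(!is.na(amount) & amount < 0)) stop_lp("amount must be non-negative")
  100 * amount / nrv_table$nrv[idx]
}

# Parse "vitamin_b12=1.0ug;iron=2.1mg" declarations; a bare nutrient name
# declares fortification with unknown amount.
#' Parse a fortificant declaration string
#'
#' @param text semicolon-separated list, e.g.
#'   \code{"vitamin_b12=1.0ug;iron=2.1mg"}; empty for none.
#' @return data.frame with \code{nutrient}, \code{amount} (NA when unknown),
#'   \code{unit}.
#' @export
parse_fortificants <- function(text) {
  empty <- data.frame(nutrient = character(0), amount = numeric(0),
                      unit = character(0), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  parts <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  rows <- lapply(parts, function(p) {
    m <- regmatches(p, regexec(
      "^([a-z0-9_]+)(?:=([0-9]+(?:[.,][0-9]+)?)[ ]*(ug|µg|mcg|mg|g)?)?$",
      p, ignore.case = TRUE))[[1]]
    if (length(m) == 0) stop_lp("cannot parse fortificant token '%s'", p)
    data.frame(nutrient = tolower(m[2]),
               amount = if (nzchar(m[3])) as.numeric(gsub(",", ".", m[3]))
                        else NA_real_,
               unit = if (nzchar(m[4])) tolower(m[4]) else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# convert an amount to the target unit (ug/mg/g ladder)
.convert_unit <- function(amount, from, to) {
  factor_ug <- c(ug = 1, "µg" = 1, mcg = 1, mg = 1000, g = 1e6)
  amount * factor_ug[[from]] / factor_ug[[to]]
}

#' Fortification records for a cohort
#'
#' Parses every product's fortificant declarations, converts amounts to the
#' NRV unit and computes coverage. Iron that appears in the nutrient
#' declaration but not in the ingredient list is annotated as naturally
#' occurring rather than added.
#'
#' @param products validated products data.frame.
#' @param nrv_table NRV table.
#' @return data.frame: one row per (product, declared nutrient) with
#'   \code{amount} (in the NRV unit), \code{nrv_coverage_percent},
#'   \code{declared_as_added}.
#' @export
fortification_records <- function(products, nrv_table = default_nrv_table()) {
  rows <- lapply(seq_len(nrow(products)), function(i) {
    f <- parse_fortificants(products$fortificants[i])
    if (nrow(f) == 0) return(NULL)
    cbind(product_id = products$product_id[i],
          subcategory = products$subcategory[i],
          arm = products$arm[i], f,
          ingredients_text = products$ingredients_text[i])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(product_id = character(0), subcategory = character(0),
                      arm = character(0), nutrient = character(0),
                      amount = numeric(0), unit = character(0),
                      nrv_coverage_percent = numeric(0),
                      declared_as_added = logical(0)))
  }
  out <- do.call(rbind, rows)
  idx <- match(out$nutrient, nrv_table$nutrient)
  if (any(is.na(idx))) {
    stop_lp("no NRV entry for nutrient(s): %s",
            paste(unique(out$nutrient[is.na(idx)]), collapse = ", "))
  }
  known <- !is.na(out$amount)
  out$amount[known] <- vapply(which(known), function(i) {
    .convert_unit(out$amount[i], out$unit[i] %||% nrv_table$unit[idx[i]],
                  nrv_table$unit[idx[i]])
  }, numeric(1))
  out$unit <- nrv_table$unit[idx]
  out$nrv_coverage_percent <- ifelse(known,
                                     nrv_coverage(out$nutrient, out$amount,
                                                  nrv_table), NA_real_)
  # iron present in the declaration but absent from the ingredient list is
  # reported as naturally occurring, not fortification
  ing <- tolower(out$ingredients_text)
  out$declared_as_added <- !(out$nutrient == "iron" & !grepl("iron", ing,
                                                             fixed = TRUE))
  out$ingredients_text <- NULL
  rownames(out) <- NULL
  out
}

#' Additive lexicon
#'
#' Label tokens and E-numbers mapped to functional classes (thickener,
#' stabilizer, acid regulator, colorant, preservative, emulsifier,
#' antioxidant, other). The shipped lexicon is a constructed superset built
#' from the survey's named examples and common EU additives; it is data, not
#' code, and can be replaced by any JSON of the same shape.
#'
#' @param path JSON file; defaults to the shipped lexicon.
#' @return data.frame with columns \code{token}, \code{e_number},
#'   \code{functional_class}.
#' @export
default_additive_lexicon <- function(path = system.file(
  "extdata", "additive_lexicon.json", package = "labelprofiler")) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(x$entries)
}

#' Annotate additives and flavourings in an ingredient list
#'
#' Splits the ingredient list on commas and matches lexicon tokens and
#' E-numbers case-insensitively within each segment. Duplicate mentions of an
#' additive count once (idempotent). Two special rules: paprika extract is
#' counted as a colorant only when its colouring function is explicitly
#' stated in the same segment (e.g. "colouring paprika extract"), otherwise
#' it is annotated but exempt; flavouring mentions ("flavouring", "aroma")
#' are flagged separately and never counted as additives.
#'
#' @param ingredients_text free-text ingredient list.
#' @param lexicon additive lexicon data.frame.
#' @return data.frame with \code{token}, \code{functional_class},
#'   \code{counted}, \code{is_flavouring}, \code{note}.
#' @examples
#' classify_additives("colouring paprika extract, methylcellulose")
#' @export
classify_additives <- function(ingredients_text,
                               lexicon = default_additive_lexicon()) {
  empty <- data.frame(token = character(0), functional_class = character(0),
                      counted = logical(0), is_flavouring = logical(0),
                      note = character(0), stringsAsFactors = FALSE)
  if (is.na(ingredients_text) || !nzchar(trimws(ingredients_text))) {
    return(empty)
  }
  segments <- trimws(tolower(strsplit(ingredients_text, ",",
                                      fixed = TRUE)[[1]]))
  rows <- list()
  seen <- character(0)
  for (seg in segments) {
    if (grepl("flavouring|flavoring|\\baroma\\b|\\bflavour\\b|\\bflavor\\b",
              seg)) {
      if (!"flavouring" %in% seen) {
        rows[[length(rows) + 1]] <- data.frame(
          token = "flavouring", functional_class = "other", counted = FALSE,
          is_flavouring = TRUE, note = "flavouring; not counted as additive",
          stringsAsFactors = FALSE)
        seen <- c(seen, "flavouring")
      }
      next
    }
    toks <- tolower(lexicon$token)
    enums <- tolower(gsub(" ", "", lexicon$e_number))
    seg_nospace <- gsub(" ", "", seg)
    hits <- which(vapply(seq_len(nrow(lexicon)), function(j) {
      grepl(toks[j], seg, fixed = TRUE) ||
        (nzchar(enums[j]) && grepl(enums[j], seg_nospace, fixed = TRUE))
    }, logical(1)))
    # a token that is a substring of a longer matched token in the same
    # segment (e.g. "cellulose" inside "methylcellulose") is not a hit itself
    hits <- hits[vapply(hits, function(j) {
      !any(vapply(setdiff(hits, j), function(k) {
        nchar(toks[k]) > nchar(toks[j]) && grepl(toks[j], toks[k], fixed = TRUE)
      }, logical(1)))
    }, logical(1))]
    for (j in hits) {
      if (lexicon$token[j] %in% seen) next
      counted <- TRUE
      note <- ""
      if (toks[j] == "paprika extract" && !grepl("colou?ring|färbend", seg)) {
        counted <- FALSE
        note <- "paprika extract without stated colouring function; exempt"
      }
      rows[[length(rows) + 1]] <- data.frame(
        token = lexicon$token[j],
        functional_class = lexicon$functional_class[j],
        counted = counted, is_flavouring = FALSE, note = note,
        stringsAsFactors = FALSE)
      seen <- c(seen, lexicon$token[j])
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Additive usage summary for a cohort
#'
#' Annotates every plant-arm product (the arm with ingredient lists) and
#' aggregates: distinct counted additives per product, per-subcategory means,
#' the share of additive-free products, and flavouring prevalence.
#'
#' @param products validated products data.frame.
#' @param lexicon additive lexicon.
#' @return list of class \code{additive_summary}: \code{per_product} and
#'   \code{by_subcategory} data.frames.
#' @export
additive_summary <- function(products, lexicon = default_additive_lexicon()) {
  plant <- products[products$arm == "plant", , drop = FALSE]
  ann <- lapply(plant$ingredients_text, classify_additives, lexicon = lexicon)
  per_product <- data.frame(
    product_id = plant$product_id,
    main_category = plant$main_category,
    subcategory = plant$subcategory,
    n_additives = vapply(ann, function(a) sum(a$counted), integer(1)),
    has_flavouring = vapply(ann, function(a) any(a$is_flavouring), logical(1)),
    stringsAsFactors = FALSE
  )
  by_sub <- do.call(rbind, lapply(split(per_product,
                                        per_product$subcategory), function(d) {
    data.frame(subcategory = d$subcategory[1],
               main_category = d$main_category[1],
               n = nrow(d),
               mean_additives = mean(d$n_additives),
               share_additive_free = mean(d$n_additives == 0),
               flavouring_share = mean(d$has_flavouring),
               stringsAsFactors = FALSE)
  }))
  rownames(by_sub) <- NULL
  structure(list(per_product = per_product, by_subcategory = by_sub),
            class = "additive_summary")
}

#' @export
print.additive_summary <- function(x, ...) {
  cat("Additive summary over", nrow(x$per_product), "plant-arm products\n")
  print(x$by_subcategory, digits = 3)
  invisible(x)
}
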