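# Protein-source extraction from ingredient lists and DIAAS-based quality
# classification.

#' Protein-source catalog
#'
#' Loads the shipped catalog (or a user-supplied JSON of the same shape):
#' one entry per source with a DIAAS value where the literature provides one
#' (soy 0.91; sources without a reliable published value carry NA), a
#' limiting-amino-acid group (legumes: sulphur amino acids/histidine;
#' cereals: lysine/threonine/tryptophan; potato: none), and label synonyms.
#'
#' @param path JSON file; defaults to the catalog shipped with the package.
#' @return data.frame with columns \code{source}, \code{diaas},
#'   \code{limiting_group} and list-column \code{synonyms}.
#' @export
default_protein_catalog <- function(path = system.file("extdata",
                                                       "protein_catalog.json",
                                                       package = "labelprofiler")) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- x$entries
  data.frame(
    source = vapply(entries, function(e) e$source, character(1)),
    diaas = vapply(entries, function(e) e$diaas %||% NA_real_, numeric(1)),
    limiting_group = vapply(entries, function(e) e$limiting_group, character(1)),
    synonyms = I(lapply(entries, function(e) unlist(e$synonyms))),
    stringsAsFactors = FALSE
  )
}

#' Extract protein sources from an ingredient list
#'
#' Case-insensitive fixed-string matching of catalog synonyms against the
#' free-text ingredient list, reported in listing order (by first occurrence);
#' duplicate mentions collapse to the first position. The first entry of the
#' result is the product's main protein source.
#'
#' @param ingredients_text free-text ingredient list (may be empty).
#' @param catalog protein-source catalog data.frame.
#' @return character vector of source identifiers (possibly empty).
#' @examples
#' extract_protein_sources("water, wheat gluten, pea protein isolate")
#' @export
extract_protein_sources <- function(ingredients_text,
                                    catalog = default_protein_catalog()) {
  if (nrow(catalog) == 0) stop_lp("protein catalog is empty")
  if (is.na(ingredients_text) || !nzchar(trimws(ingredients_text))) {
    return(character(0))
  }
  txt <- tolower(ingredients_text)
  pos <- vapply(seq_len(nrow(catalog)), function(i) {
    hits <- vapply(tolower(catalog$synonyms[[i]]), function(s) {
      p <- regexpr(s, txt, fixed = TRUE)
      if (p < 0) Inf else as.numeric(p)
    }, numeric(1))
    min(hits)
  }, numeric(1))
  found <- which(is.finite(pos))
  catalog$source[found[order(pos[found])]]
}

#' Classify a product's protein quality
#'
#' A product demonstrates good protein quality when any of the following
#' holds, checked in this order of precedence:
#' \enumerate{
#'   \item \code{high_diaas_source}: a source with a known DIAAS of at least
#'     \code{diaas_cutoff} (default 0.75, the usual "good source" cutoff;
#'     soy qualifies at 0.91, pea and wheat do not);
#'   \item \code{complementary_combination}: sources spanning at least two
#'     distinct limiting-amino-acid groups among legume (SAA/His) and cereal
#'     (Lys/Thr/Trp), which compensate each other's limitations;
#'   \item \code{no_limiting_aa_source}: a source without limiting amino
#'     acids, such as potato protein.
#' }
#' Otherwise the verdict is \code{not_demonstrated} with reason
#' \code{insufficient}. Relative ingredient proportions are deliberately
#' ignored. Sunflower protein is grouped "other" (lysine-limited but not a
#' cereal profile): alone it is insufficient, and with a legume it does not
#' form a complementary pair.
#'
#' @param sources ordered character vector from
#'   \code{\link{extract_protein_sources}}.
#' @param catalog protein-source catalog.
#' @param diaas_cutoff DIAAS threshold for the high-quality rule.
#' @return list of class \code{protein_quality} with \code{main_source},
#'   \code{all_sources}, \code{verdict} ("good"/"not_demonstrated") and
#'   \code{reason}.
#' @examples
#' classify_protein_quality("soy")               # good, high_diaas_source
#' classify_protein_quality(c("wheat", "pea"))   # good, complementary
#' @export
classify_protein_quality <- function(sources,
                                     catalog = default_protein_catalog(),
                                     diaas_cutoff = 0.75) {
  unknown <- setdiff(sources, catalog$source)
  if (length(unknown) > 0) {
    stop_lp("unknown protein source(s): %s", paste(unknown, collapse = ", "))
  }
  idx <- match(sources, catalog$source)
  diaas <- catalog$diaas[idx]
  groups <- catalog$limiting_group[idx]
  reason <- if (any(!is.na(diaas) & diaas >= diaas_cutoff)) {
    "high_diaas_source"
  } else if (length(intersect(groups,
                              c("legume_SAA_His", "cereal_Lys_Thr_Trp"))) >= 2) {
    "complementary_combination"
  } else if (any(groups == "none")) {
    "no_limiting_aa_source"
  } else {
    "insufficient"
  }
  structure(list(
    main_source = if (length(sources) > 0) sources[1] else NA_character_,
    all_sources = sources,
    verdict = if (reason == "insufficient") "not_demonstrated" else "good",
    reason = reason
  ), class = "protein_quality")
}

#' @export
print.protein_quality <- function(x, ...) {
  cat(sprintf("Protein quality: %s (%s); sources: %s\n", x$verdict, x$reason,
              if (length(x$all_sources)) paste(x$all_sources, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Assess protein quality for every plant-arm product
#'
#' @param products validated products data.frame.
#' @param catalog protein-source catalog.
#' @return data.frame with one row per plant-arm product: identity columns,
#'   \code{main_source}, \code{n_sources}, \code{verdict}, \code{reason}.
#' @export
assess_protein_quality <- function(products,
                                   catalog = default_protein_catalog()) {
  plant <- products[products$arm == "plant", , drop = FALSE]
  res <- lapply(plant$ingredients_text, function(txt) {
    classify_protein_quality(extract_protein_sources(txt, catalog), catalog)
  })
  data.frame(
    product_id = plant$product_id,
    main_category = plant$main_category,
    subcategory = plant$subcategory,
    main_source = vapply(res, function(r) r$main_source, character(1)),
    n_sources = vapply(res, function(r) length(r$all_sources), integer(1)),
    verdict = vapply(res, function(r) r$verdict, character(1)),
    reason = vapply(res, function(r) r$reason, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Share of products with good protein quality, by group
#'
#' @param assessments output of \code{\link{assess_protein_quality}}.
#' @param by grouping column: "subcategory", "main_category" or "overall".
#' @return data.frame with group, \code{n}, \code{n_good},
#'   \code{share_good}; empty groups are absent.
#' @export
quality_share_by_group <- function(assessments, by = c("subcategory",
                                                       "main_category",
                                                       "overall")) {
  by <- match.arg(by)
  key <- if (by == "overall") rep("overall", nrow(assessments))
         else assessments[[by]]
  if (nrow(assessments) == 0) {
    return(data.frame(group = character(0), n = integer(0),
                      n_good = integer(0), share_good = numeric(0)))
  }
  agg <- stats::aggregate(list(n = assessments$verdict),
                          by = list(group = key), FUN = length)
  good <- stats::aggregate(list(n_good = assessments$verdict == "good"),
                           by = list(group = key), FUN = sum)
  out <- merge(agg, good, by = "group")
  out$share_good <- out$n_good / out$n
  out
}
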