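# End-to-end report surfaces: per-cell nutrient summaries with pairwise
# tests, Nutri-Score distributions, multivariate (PCA + PERMANOVA) reports,
# and a run_pipeline() orchestrator that writes everything to disk.

SUMMARY_NUTRIENTS <- c("energy_kcal", "energy_kj", "fat_g", "satfat_g",
                       "cho_g", "sugar_g", "fibre_g", "protein_g", "salt_g")
# nutrients entering the pairwise tests (energy once, on the kcal scale;
# ranks are identical on either energy scale)
TESTED_NUTRIENTS <- c("energy_kcal", "fat_g", "satfat_g", "cho_g", "sugar_g",
                      "fibre_g", "protein_g", "salt_g")
# features of the multivariate analyses; fibre excluded by design
PCA_FEATURES <- c("energy_kcal", "fat_g", "satfat_g", "cho_g", "sugar_g",
                  "protein_g", "salt_g")

# subcategories of a cohort that have both arms, in scheme order
.paired_subcategories <- function(products) {
  tab <- subcategory_table()
  present <- intersect(tab$subcategory, unique(products$subcategory))
  present[vapply(present, function(s) {
    arms <- unique(products$arm[products$subcategory == s])
    all(c("plant", "animal") %in% arms)
  }, logical(1))]
}

#' Per-subcategory nutrient summaries with pairwise tests
#'
#' Mean, SD, median and n per (subcategory, arm) cell for every nutrient
#' (energy on both scales), plus plant-vs-animal Mann-Whitney tests per
#' subcategory per nutrient with Bonferroni adjustment. Fibre summary
#' statistics use declared or reliably imputed values only (unreliable
#' imputations keep their scoring floor but are excluded here). Subcategories
#' with a single arm are skipped with a notice.
#'
#' @param products validated products data.frame.
#' @param family Bonferroni family: \code{"per_nutrient"} (family size = the
#'   number of paired subcategories, as in the reference survey's summary
#'   table) or \code{"per_cell"} (subcategories x nutrients).
#' @return list of class \code{summary_tables}: \code{cells} (long summary),
#'   \code{tests} (statistics and raw/adjusted p-values), \code{skipped}.
#' @export
run_summary_tables <- function(products,
                               family = c("per_nutrient", "per_cell")) {
  family <- match.arg(family)
  fibre_ok <- (products$fibre_status %||% rep("declared", nrow(products))) ==
    "declared" | (products$fibre_reliable %||% rep(TRUE, nrow(products)))
  cells <- list()
  for (s in unique(products$subcategory)) {
    for (a in unique(products$arm[products$subcategory == s])) {
      rows <- products$subcategory == s & products$arm == a
      for (nut in SUMMARY_NUTRIENTS) {
        v <- products[[nut]][rows]
        if (nut == "fibre_g") v <- v[fibre_ok[rows]]
        v <- v[!is.na(v)]
        cells[[length(cells) + 1]] <- data.frame(
          subcategory = s, arm = a, nutrient = nut, n = length(v),
          mean = mean(v), sd = stats::sd(v), median = stats::median(v),
          stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, cells)
  paired <- .paired_subcategories(products)
  skipped <- setdiff(unique(products$subcategory), paired)
  tests <- list()
  for (s in paired) {
    for (nut in TESTED_NUTRIENTS) {
      keep <- products$subcategory == s & !is.na(products[[nut]])
      if (nut == "fibre_g") keep <- keep & fibre_ok
      x <- products[[nut]][keep & products$arm == "plant"]
      y <- products[[nut]][keep & products$arm == "animal"]
      mw <- mann_whitney_u(x, y)
      tests[[length(tests) + 1]] <- data.frame(
        subcategory = s, nutrient = nut, n_plant = length(x),
        n_animal = length(y), U = mw$U, p_raw = mw$p,
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  if (!is.null(tests)) {
    m <- if (family == "per_nutrient") length(paired)
         else length(paired) * length(TESTED_NUTRIENTS)
    tests$p_adjusted <- bonferroni(tests$p_raw, m)
    tests$family_size <- m
    tests$adjustment <- "bonferroni"
  }
  structure(list(cells = cells, tests = tests, skipped = skipped,
                 family = family),
            class = "summary_tables")
}

#' @export
print.summary_tables <- function(x, ...) {
  cat("Nutrient summary:", length(unique(x$cells$subcategory)),
      "subcategories;", nrow(x$tests %||% data.frame()), "pairwise tests",
      sprintf("(Bonferroni, %s family)\n", x$family))
  if (length(x$skipped)) {
    cat("Skipped (single arm):", paste(x$skipped, collapse = ", "), "\n")
  }
  sig <- x$tests[!is.na(x$tests$p_adjusted) & x$tests$p_adjusted < 0.05, ]
  cat(nrow(sig), "comparisons significant at adjusted p < 0.05\n")
  invisible(x)
}

#' Nutri-Score report for a cohort
#'
#' Per-product FSAm-NPS breakdowns, grade distributions per (subcategory,
#' arm) and per (main category, arm), and plant-vs-animal Mann-Whitney tests
#' on the FSAm-NPS total score per subcategory with Bonferroni adjustment.
#'
#' @param products validated products data.frame.
#' @return list of class \code{nutriscore_report}: \code{scores},
#'   \code{grade_shares}, \code{tests}, \code{skipped}.
#' @export
run_nutriscore_report <- function(products) {
  scores <- score_products(products)
  share_block <- function(d, level, group) {
    shares <- vapply(c("A", "B", "C", "D", "E"),
                     function(g) mean(d$grade == g), numeric(1))
    data.frame(level = level, group = group, arm = d$arm[1], n = nrow(d),
               grade = names(shares), share = as.vector(shares),
               stringsAsFactors = FALSE)
  }
  blocks <- list()
  for (s in unique(scores$subcategory)) {
    for (a in unique(scores$arm[scores$subcategory == s])) {
      blocks[[length(blocks) + 1]] <-
        share_block(scores[scores$subcategory == s & scores$arm == a, ],
                    "subcategory", s)
    }
  }
  for (mc in unique(scores$main_category)) {
    for (a in unique(scores$arm[scores$main_category == mc])) {
      blocks[[length(blocks) + 1]] <-
        share_block(scores[scores$main_category == mc & scores$arm == a, ],
                    "main_category", mc)
    }
  }
  grade_shares <- do.call(rbind, blocks)
  paired <- .paired_subcategories(products)
  tests <- lapply(paired, function(s) {
    x <- scores$total_score[scores$subcategory == s & scores$arm == "plant"]
    y <- scores$total_score[scores$subcategory == s & scores$arm == "animal"]
    mw <- mann_whitney_u(x, y)
    data.frame(subcategory = s, n_plant = length(x), n_animal = length(y),
               median_plant = stats::median(x), median_animal = stats::median(y),
               U = mw$U, p_raw = mw$p, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  if (!is.null(tests)) {
    tests$p_adjusted <- bonferroni(tests$p_raw, length(paired))
    tests$family_size <- length(paired)
  }
  structure(list(scores = scores, grade_shares = grade_shares, tests = tests,
                 skipped = setdiff(unique(products$subcategory), paired)),
            class = "nutriscore_report")
}

#' @export
print.nutriscore_report <- function(x, ...) {
  cat("Nutri-Score report:", nrow(x$scores), "products scored\n")
  overall <- x$grade_shares[x$grade_shares$level == "main_category", ]
  for (key in unique(paste(overall$group, overall$arm))) {
    d <- overall[paste(overall$group, overall$arm) == key, ]
    cat(sprintf("  %-16s %s\n", key,
                paste(sprintf("%s %2.0f%%", d$grade, 100 * d$share),
                      collapse = " ")))
  }
  invisible(x)
}

#' Multivariate report: PCA and per-subcategory PERMANOVA
#'
#' Meat and sausage main categories are analysed separately. The feature
#' matrix holds energy (kcal), fat, saturated fat, carbohydrate, sugar,
#' protein and salt; fibre is excluded by design. Each paired subcategory is
#' compared plant vs animal by two-group PERMANOVA on Euclidean distances of
#' the scaled features, with Bonferroni adjustment over the number of
#' subcategories tested within the main category.
#'
#' @param products validated products data.frame.
#' @param n_perm permutations per PERMANOVA (default 9999).
#' @param seed integer seed; sub-seeds are derived deterministically per
#'   comparison.
#' @param scale scale features to unit variance before distances.
#' @return list of class \code{multivariate_report}, one element per main
#'   category with \code{pca} and \code{permanova} (data.frame).
#' @export
run_multivariate_report <- function(products, n_perm = 9999, seed = 1,
                                    scale = TRUE) {
  out <- list()
  for (mc in intersect(c("meat", "sausage"), unique(products$main_category))) {
    d <- products[products$main_category == mc, , drop = FALSE]
    pca <- pca_scaled(d[PCA_FEATURES])
    paired <- .paired_subcategories(d)
    rows <- list()
    for (k in seq_along(paired)) {
      s <- paired[k]
      dd <- d[d$subcategory == s, , drop = FALSE]
      sub_seed <- (seed * 131 + k * 7919) %% .Machine$integer.max
      pm <- permanova_two_group(dd[PCA_FEATURES], dd$arm, n_perm = n_perm,
                                seed = sub_seed, scale = scale)
      rows[[k]] <- data.frame(
        main_category = mc, subcategory = s,
        n_plant = sum(dd$arm == "plant"), n_animal = sum(dd$arm == "animal"),
        pseudo_F = pm$pseudo_F, r_squared = pm$r_squared, p_perm = pm$p_perm,
        n_permutations = n_perm, seed = sub_seed, stringsAsFactors = FALSE)
    }
    perm <- do.call(rbind, rows)
    if (!is.null(perm)) {
      perm$p_adjusted <- bonferroni(perm$p_perm, length(paired))
      perm$family_size <- length(paired)
    }
    out[[mc]] <- list(pca = pca, permanova = perm)
  }
  structure(out, class = "multivariate_report")
}

#' @export
print.multivariate_report <- function(x, ...) {
  for (mc in names(x)) {
    ve <- x[[mc]]$pca$variance_explained
    cat(sprintf("%s: Dim1+Dim2 explain %.1f%% of variance\n", mc,
                100 * sum(ve[1:2])))
    if (!is.null(x[[mc]]$permanova)) print(x[[mc]]$permanova, digits = 4)
  }
  invisible(x)
}

#' Run the full profiling pipeline
#'
#' Loads a products CSV or generates a synthetic cohort, computes all report
#' surfaces (nutrient summaries with tests, Nutri-Score report, multivariate
#' report, protein quality, fortification, additives) and writes them as CSV
#' files plus a markdown digest into \code{out_dir}. Deterministic per seed;
#' every reported number is recomputable from the emitted per-product files.
#'
#' @param input path to a products CSV, or \code{NULL} to use
#'   \code{config}.
#' @param config a \code{cohort_config} (or path to its JSON) used when
#'   \code{input} is \code{NULL}; exactly one of the two sources must be
#'   given.
#' @param seed integer seed for cohort generation and permutation tests.
#' @param out_dir output directory, created if needed; \code{NULL} to skip
#'   writing.
#' @param n_perm PERMANOVA permutations.
#' @param family Bonferroni family mode for nutrient tests.
#' @param plots also write basic figures (grade bars, PCA biplot) as PDF.
#' @return invisible list with \code{products}, \code{summary},
#'   \code{nutriscore}, \code{multivariate}, \code{protein_quality},
#'   \code{quality_shares}, \code{fortification}, \code{additives}.
#' @export
run_pipeline <- function(input = NULL, config = NULL, seed = 1,
                         out_dir = NULL, n_perm = 9999,
                         family = "per_nutrient", plots = FALSE) {
  if (is.null(input) == is.null(config)) {
    stop_lp("provide exactly one of `input` (CSV path) or `config` (synthetic)")
  }
  products <- if (!is.null(input)) {
    read_products_csv(input)
  } else {
    if (is.character(config)) config <- config_from_json(config)
    generate_cohort(config, seed = seed)
  }
  summary_tab <- run_summary_tables(products, family = family)
  ns <- run_nutriscore_report(products)
  mv <- run_multivariate_report(products, n_perm = n_perm, seed = seed)
  pq <- assess_protein_quality(products)
  shares <- quality_share_by_group(pq, by = "subcategory")
  fort <- fortification_records(products)
  adds <- additive_summary(products)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
    write_products_csv(products, file.path(out_dir, "products.csv"))
    w(summary_tab$cells, "summary_cells.csv")
    w(summary_tab$tests, "summary_tests.csv")
    w(ns$scores, "scores.csv")
    w(ns$grade_shares, "grade_shares.csv")
    w(ns$tests, "score_tests.csv")
    for (mc in names(mv)) {
      ve <- mv[[mc]]$pca$variance_explained
      w(data.frame(dimension = seq_along(ve), variance_explained = ve),
        sprintf("pca_%s_variance.csv", mc))
      w(as.data.frame(mv[[mc]]$pca$contributions),
        sprintf("pca_%s_contributions.csv", mc))
      w(mv[[mc]]$permanova, sprintf("permanova_%s.csv", mc))
    }
    w(pq, "protein_quality.csv")
    w(shares, "quality_shares.csv")
    w(fort, "fortification.csv")
    w(adds$per_product, "additives_per_product.csv")
    w(adds$by_subcategory, "additive_summary.csv")
    .write_digest(file.path(out_dir, "digest.md"), products, summary_tab, ns,
                  mv, shares, fort, adds, seed, n_perm)
    if (plots) .write_plots(out_dir, ns, mv)
  }
  invisible(list(products = products, summary = summary_tab, nutriscore = ns,
                 multivariate = mv, protein_quality = pq,
                 quality_shares = shares, fortification = fort,
                 additives = adds))
}

.write_digest <- function(path, products, summary_tab, ns, mv, shares, fort,
                          adds, seed, n_perm) {
  lines <- c(
    "# Label profiling run digest", "",
    sprintf("- products: %d (%d plant / %d animal), seed %d",
            nrow(products), sum(products$arm == "plant"),
            sum(products$arm == "animal"), seed),
    sprintf("- nutrient comparisons: %d, Bonferroni family %s",
            nrow(summary_tab$tests %||% data.frame()), summary_tab$family),
    sprintf("- FSAm-NPS comparisons significant (adj. p < 0.05): %d of %d",
            sum(ns$tests$p_adjusted < 0.05), nrow(ns$tests)),
    "")
  for (mc in names(mv)) {
    ve <- mv[[mc]]$pca$variance_explained
    lines <- c(lines, sprintf(
      "- %s PCA: Dim1 %.1f%%, Dim2 %.1f%% (Dim1+Dim2 %.1f%%); PERMANOVA x%d per subcategory (%d permutations)",
      mc, 100 * ve[1], 100 * ve[2], 100 * sum(ve[1:2]),
      nrow(mv[[mc]]$permanova %||% data.frame()), n_perm))
  }
  n_plant <- sum(products$arm == "plant")
  good <- sum(shares$n_good) / max(1, sum(shares$n))
  lines <- c(lines,
             sprintf("- protein quality: %.0f%% of plant-arm products good",
                     100 * good),
             sprintf("- fortified plant-arm products: %d of %d",
                     length(unique(fort$product_id[fort$arm == "plant"])),
                     n_plant),
             sprintf("- mean additives per plant-arm product: %.2f",
                     mean(adds$per_product$n_additives)))
  writeLines(lines, path)
}

.write_plots <- function(out_dir, ns, mv) {
  grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 8, height = 5)
  on.exit(grDevices::dev.off())
  gs <- ns$grade_shares[ns$grade_shares$level == "main_category", ]
  for (key in unique(paste(gs$group, gs$arm))) {
    d <- gs[paste(gs$group, gs$arm) == key, ]
    graphics::barplot(d$share, names.arg = d$grade,
                      main = paste("Nutri-Score grades:", key),
                      ylab = "share", col = c("darkgreen", "green3", "gold",
                                              "orange", "orangered"))
  }
  for (mc in names(mv)) {
    sc <- mv[[mc]]$pca$scores
    graphics::plot(sc[, 1], sc[, 2], xlab = "Dim1", ylab = "Dim2",
                   main = paste("PCA:", mc), pch = 19, cex = 0.6)
  }
  invisible(NULL)
}
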