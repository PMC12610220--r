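# Comparison layer: Mann-Whitney U with exact small-sample enumeration,
# Bonferroni adjustment, scaled PCA, and two-group PERMANOVA on Euclidean
# distances. The rank test and the PERMANOVA are implemented from their
# defining computations; stats::wilcox.test and vegan::adonis2 serve as
# independent cross-checks in the test suite.

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from rank sums with midrank tie handling. For small samples
#' (\code{n_x + n_y <= exact_limit}, default 10) the two-sided p-value comes
#' from exhaustive enumeration of all group labelings of the pooled sample
#' (valid under ties); otherwise from the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_limit pooled-size limit for the exact path.
#' @return list with \code{U} (statistic for the first sample),
#'   \code{p} (two-sided) and \code{method}.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_limit = 10) {
  if (length(x) == 0 || length(y) == 0) stop_lp("samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (n <= exact_limit) {
    dev_obs <- abs(U - mu)
    combos <- utils::combn(n, nx)
    devs <- apply(combos, 2, function(idx) {
      abs(sum(r[idx]) - nx * (nx + 1) / 2 - mu)
    })
    p <- mean(devs >= dev_obs - 1e-9)
    return(list(U = U, p = p, method = "exact enumeration"))
  }
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "degenerate (all tied)"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  if (U == mu) z <- 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "normal approximation, tie-corrected")
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size and caps at 1. The family size
#' defaults to the number of p-values (then identical to
#' \code{stats::p.adjust(..., "bonferroni")}) but can be set explicitly,
#' e.g. to the number of subcategory comparisons within a nutrient.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param m family size (>= 1).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop_lp("p-values must lie in [0, 1]")
  if (m < 1) stop_lp("family size must be at least 1")
  pmin(1, p * m)
}

#' PCA on scaled data
#'
#' Columns are centered and scaled to unit variance (correlation-structure
#' PCA via \code{stats::prcomp}); reports the variance share of each
#' dimension and the per-variable contributions (squared loadings, which sum
#' to 1 within each dimension). By the survey's design the fibre column is
#' excluded from the feature matrix before calling this function: fibre has
#' low variability among analogues and is near-absent in animal products.
#'
#' @param x numeric matrix or data.frame, products x nutrients, at least 2x2,
#'   no zero-variance column.
#' @return object of class \code{pca_scaled}: \code{loadings}, \code{scores},
#'   \code{sdev}, \code{variance_explained} (sums to 1), \code{contributions}
#'   (each column sums to 1).
#' @export
pca_scaled <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop_lp("PCA needs at least 2 rows and 2 columns")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop_lp("zero-variance column(s): %s",
            paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  contrib <- sweep(pr$rotation^2, 2, colSums(pr$rotation^2), "/")
  structure(list(loadings = pr$rotation, scores = pr$x, sdev = pr$sdev,
                 variance_explained = ve, contributions = contrib),
            class = "pca_scaled")
}

#' @export
print.pca_scaled <- function(x, ...) {
  k <- min(4, length(x$variance_explained))
  cat("Scaled PCA:", ncol(x$loadings), "dimensions\n")
  cat("Variance explained:",
      paste(sprintf("Dim%d %.1f%%", seq_len(k),
                    100 * x$variance_explained[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

# Sums of squares from a squared Euclidean distance matrix for a labeling:
# SS_within = sum over groups of (within-group squared distances)/(2*n_g);
# SS_total = all squared distances/(2*n). Between = total - within.
.permanova_ss <- function(D2, labels) {
  n <- nrow(D2)
  sst <- sum(D2) / (2 * n)
  ssw <- 0
  for (g in unique(labels)) {
    i <- which(labels == g)
    ssw <- ssw + sum(D2[i, i]) / (2 * length(i))
  }
  c(between = sst - ssw, within = ssw, total = sst)
}

#' Two-group PERMANOVA on Euclidean distances
#'
#' Permutational multivariate analysis of variance for two groups:
#' pseudo-F = (SS_between/(g-1)) / (SS_within/(n-g)) with g = 2, computed
#' from the squared Euclidean distance matrix; R^2 = SS_between/SS_total;
#' the p-value is \code{(#{F_perm >= F_obs} + 1)/(n_perm + 1)} over random
#' label permutations (sampled without enforcing uniqueness, standard
#' practice at 9,999 permutations). Columns are scaled to unit variance by
#' default so the distance reuses the PCA scaling; set \code{scale = FALSE}
#' for raw features.
#'
#' @param points numeric matrix, rows = products, columns = features.
#' @param labels two-level factor/character vector, both groups non-empty.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for the permutation draw.
#' @param scale scale columns to unit variance first (default TRUE).
#' @return object of class \code{permanova}: \code{pseudo_F},
#'   \code{r_squared}, \code{p_perm}, \code{n_permutations}, \code{seed},
#'   \code{ss} (between/within/total), group sizes.
#' @export
permanova_two_group <- function(points, labels, n_perm = 9999, seed = 1,
                                scale = TRUE) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  counts <- table(labels)
  if (length(counts) != 2) stop_lp("labels must define exactly two groups")
  if (any(counts == 0)) stop_lp("both groups must be non-empty")
  if (n_perm < 1) stop_lp("n_perm must be at least 1")
  n <- nrow(points)
  if (n < 3) stop_lp("need at least 3 observations")
  if (scale) {
    sds <- apply(points, 2, stats::sd)
    if (any(sds == 0)) stop_lp("zero-variance column; cannot scale")
    points <- base::scale(points)
  }
  D2 <- as.matrix(stats::dist(points))^2
  ss <- .permanova_ss(D2, labels)
  f_stat <- function(s) (s[["between"]] / 1) / (s[["within"]] / (n - 2))
  F_obs <- f_stat(ss)
  F_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      f_stat(.permanova_ss(D2, sample(labels)))
    }, numeric(1))
  })
  p <- (sum(F_perm >= F_obs - 1e-12) + 1) / (n_perm + 1)
  structure(list(pseudo_F = F_obs, r_squared = ss[["between"]] / ss[["total"]],
                 p_perm = p, n_permutations = n_perm, seed = seed,
                 ss = ss, n = as.vector(counts),
                 groups = names(counts)), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (%s vs %s, n = %d/%d): F = %.3f, R2 = %.4f, p = %.4g (%d permutations)\n",
    x$groups[1], x$groups[2], x$n[1], x$n[2], x$pseudo_F, x$r_squared,
    x$p_perm, x$n_permutations))
  invisible(x)
}
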