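test_that("Mann-Whitney U matches hand-derived small-sample results", {
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 0.1)  # 2 of the 20 labelings are as extreme
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("U statistics of the two samples sum to nx*ny", {
  set.seed(5)
  for (i in 1:30) {
    x <- round(rnorm(sample(2:12, 1)), 1)
    y <- round(rnorm(sample(2:12, 1)), 1)
    ux <- mann_whitney_u(x, y)$U
    uy <- mann_whitney_u(y, x)$U
    expect_equal(ux + uy, length(x) * length(y))
  }
})

test_that("small-sample p-values agree with exhaustive enumeration", {
  set.seed(23)
  for (i in 1:40) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    # draw from a small value set to provoke ties
    x <- sample(1:4, nx, replace = TRUE)
    y <- sample(1:4, ny, replace = TRUE)
    got <- mann_whitney_u(x, y)$p
    expect_lt(abs(got - mw_exact_oracle(x, y)), 0.01)
  }
})

test_that("large-sample path matches the tie-corrected normal approximation", {
  set.seed(29)
  for (i in 1:20) {
    x <- round(rnorm(sample(12:30, 1), 0, 2), 1)
    y <- round(rnorm(sample(12:30, 1), 0.8, 2), 1)
    got <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Bonferroni adjustment multiplies and caps at 1", {
  expect_equal(bonferroni(0.01, 9), 0.09)
  expect_equal(bonferroni(0.5, 9), 1)
  expect_equal(bonferroni(c(0.001, 0.2, 0.9)), c(0.003, 0.6, 1))
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("scaled PCA reproduces closed-form 2-column eigenstructure", {
  x <- matrix(c(1, 2, 3, 4), ncol = 1)
  perfect <- pca_scaled(cbind(a = x, b = 2 * x))
  expect_equal(perfect$variance_explained[1], 1)

  m <- cbind(u = c(2.1, 3.7, 1.2, 5.5), v = c(1.0, 2.2, 0.7, 3.9))
  r <- cor(m)[1, 2]
  got <- pca_scaled(m)
  # 2x2 correlation matrix has eigenvalues 1 + r and 1 - r
  expect_equal(sort(got$sdev^2, decreasing = TRUE), c(1 + r, 1 - r),
               tolerance = 1e-8)
  expect_equal(sum(got$variance_explained), 1)
  expect_equal(unname(colSums(got$contributions)), rep(1, 2))
})

test_that("PCA variance shares are invariant to row permutation", {
  set.seed(3)
  m <- matrix(rnorm(60), ncol = 4)
  a <- pca_scaled(m)
  b <- pca_scaled(m[sample(nrow(m)), ])
  expect_equal(a$variance_explained, b$variance_explained, tolerance = 1e-12)
  expect_error(pca_scaled(cbind(m, const = 1)), "zero-variance")
})

test_that("PERMANOVA conserves sums of squares and is seed-stable", {
  set.seed(41)
  pts <- matrix(rnorm(40), ncol = 4)
  lab <- rep(c("a", "b"), each = 5)
  res <- permanova_two_group(pts, lab, n_perm = 99, seed = 7)
  expect_equal(res$ss[["between"]] + res$ss[["within"]], res$ss[["total"]],
               tolerance = 1e-9)
  expect_true(res$r_squared >= 0 && res$r_squared <= 1)
  expect_gte(res$p_perm, 1 / (res$n_permutations + 1))
  res2 <- permanova_two_group(pts, lab, n_perm = 99, seed = 7)
  expect_identical(res$p_perm, res2$p_perm)
})

test_that("identical groups give vanishing F and p of 1", {
  pts <- rbind(diag(3), diag(3))
  lab <- rep(c("a", "b"), each = 3)
  res <- permanova_two_group(pts, lab, n_perm = 199, seed = 1, scale = FALSE)
  expect_lt(abs(res$pseudo_F), 1e-8)
  expect_gt(res$p_perm, 0.95)
})

test_that("sampled permutation p matches exhaustive label enumeration", {
  set.seed(17)
  pts <- matrix(rnorm(12, sd = 1) + rep(c(0, 1.5), each = 6), ncol = 2)
  lab <- rep(c("a", "b"), each = 3)
  # exhaustive two-group enumeration over all C(6,3) = 20 assignments
  D2 <- as.matrix(dist(scale(pts)))^2
  f_of <- function(l) {
    n <- length(l)
    sst <- sum(D2) / (2 * n)
    ssw <- sum(vapply(unique(l), function(g) {
      i <- which(l == g); sum(D2[i, i]) / (2 * length(i))
    }, numeric(1)))
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  combos <- utils::combn(6, 3)
  f_all <- apply(combos, 2, function(idx) {
    l <- rep("b", 6); l[idx] <- "a"; f_of(l)
  })
  f_obs <- f_of(lab)
  p_exact <- mean(f_all >= f_obs - 1e-12)
  res <- permanova_two_group(pts, lab, n_perm = 9999, seed = 3)
  mc_err <- 3 * sqrt(p_exact * (1 - p_exact) / 9999) + 2 / 9999
  expect_lt(abs(res$p_perm - p_exact), mc_err + 0.01)
  expect_equal(res$pseudo_F, f_obs, tolerance = 1e-10)
})

test_that("R2 is invariant to rigid motion and F to global scaling", {
  set.seed(53)
  pts <- matrix(rnorm(30), ncol = 3)
  lab <- rep(c("a", "b"), each = 5)
  base <- permanova_two_group(pts, lab, n_perm = 49, seed = 2, scale = FALSE)
  th <- 0.7
  rot <- diag(3); rot[1:2, 1:2] <- matrix(c(cos(th), sin(th),
                                            -sin(th), cos(th)), 2)
  moved <- pts %*% rot + matrix(rep(c(5, -3, 2), each = 10), ncol = 3)
  res_rot <- permanova_two_group(moved, lab, n_perm = 49, seed = 2,
                                 scale = FALSE)
  expect_equal(res_rot$r_squared, base$r_squared, tolerance = 1e-9)
  res_scaled <- permanova_two_group(pts * 3.7, lab, n_perm = 49, seed = 2,
                                    scale = FALSE)
  expect_equal(res_scaled$pseudo_F, base$pseudo_F, tolerance = 1e-9)
})

test_that("PERMANOVA agrees with the vegan implementation", {
  set.seed(61)
  pts <- matrix(rnorm(48), ncol = 4)
  grp <- rep(c("a", "b"), each = 6)
  res <- permanova_two_group(pts, grp, n_perm = 199, seed = 5, scale = FALSE)
  ref <- vegan::adonis2(dist(pts) ~ grp, permutations = 199)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-8)
  expect_equal(res$r_squared, ref$R2[1], tolerance = 1e-8)
  expect_lt(abs(res$p_perm - ref$`Pr(>F)`[1]), 0.15)
})
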