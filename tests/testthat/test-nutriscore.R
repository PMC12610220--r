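make_panel <- function(energy_kj = 0, satfat = 0, sugar = 0, salt = 0,
                       protein = 0, fibre = 0) {
  list(energy_kj = energy_kj, satfat_g = satfat, sugar_g = sugar,
       salt_g = salt, protein_g = protein, fibre_g = fibre)
}

test_that("component points follow the 2023 tables with strict thresholds", {
  expect_equal(component_points("energy_kj", 0), 0)
  expect_equal(component_points("salt_g", 4.2), 20)
  expect_equal(component_points("protein_g", 18), 7)
  # values exactly on a threshold do not earn the point
  expect_equal(component_points("salt_g", 4.0), 19)
  expect_equal(component_points("sugars_g", 3.4), 0)
  expect_equal(component_points("sugars_g", 3.41), 1)
  expect_equal(component_points("fibre_g", 7.5), 5)
  expect_equal(component_points("fvl_percent", c(40, 41, 61, 81)), c(0, 1, 2, 5))
  expect_error(component_points("cholesterol", 1), "unknown nutrient")
  expect_error(component_points("salt_g", -1), "non-negative")
})

test_that("total score spans the published extremes", {
  zero <- compute_fsam_nps(make_panel())
  expect_equal(zero$total_score, 0)
  expect_equal(zero$grade, "A")
  worst <- compute_fsam_nps(make_panel(energy_kj = 3360, satfat = 11,
                                       sugar = 52, salt = 4.2))
  expect_equal(worst$total_score, 55)
  expect_equal(worst$n_unfavourable, 55)
  expect_false(worst$protein_counted)
  best <- compute_fsam_nps(make_panel(protein = 18, fibre = 8),
                           fvl_percent = 85)
  expect_equal(best$total_score, -17)
  expect_equal(best$grade, "A")
  expect_equal(score_bounds(), c(-17, 55))
})

test_that("red-meat protein cap and preparation-salt rule apply", {
  uncapped <- compute_fsam_nps(make_panel(protein = 25))
  capped <- compute_fsam_nps(make_panel(protein = 25), red_meat_derived = TRUE)
  expect_equal(uncapped$protein_pts, 7)
  expect_true(capped$protein_capped)
  expect_equal(capped$total_score - uncapped$total_score, 5)

  plain <- compute_fsam_nps(make_panel(salt = 0.3))
  salted <- compute_fsam_nps(make_panel(salt = 0.3), salt_added_in_prep = TRUE)
  expect_equal(plain$salt_pts, 1)     # 0.3 scored as declared
  expect_equal(salted$salt_pts, 3)    # scored at 0.8
  expect_true(salted$salt_adjustment_applied)
})

test_that("protein counts only when N < 11 or FVL is at maximum", {
  set.seed(31)
  for (i in 1:200) {
    p <- make_panel(energy_kj = runif(1, 0, 3600), satfat = runif(1, 0, 12),
                    sugar = runif(1, 0, 55), salt = runif(1, 0, 4.5),
                    protein = runif(1, 0, 20), fibre = runif(1, 0, 9))
    fvl <- sample(c(0, 45, 65, 85), 1)
    b <- compute_fsam_nps(p, fvl_percent = fvl)
    expect_equal(b$protein_counted, b$n_unfavourable < 11 | b$fvl_pts == 5)
    expect_equal(b$total_score, b$n_unfavourable - b$p_favourable)
    expect_true(b$total_score >= -17 && b$total_score <= 55)
  }
})

test_that("score is monotone in unfavourable nutrients and in fibre", {
  set.seed(13)
  for (i in 1:60) {
    p <- make_panel(energy_kj = runif(1, 0, 3000), satfat = runif(1, 0, 10),
                    sugar = runif(1, 0, 50), salt = runif(1, 0, 4),
                    protein = runif(1, 0, 20), fibre = runif(1, 0, 8))
    base <- compute_fsam_nps(p)$total_score
    for (comp in c("energy_kj", "satfat_g", "sugar_g", "salt_g")) {
      q <- p
      q[[comp]] <- q[[comp]] * (1 + runif(1, 0, 1)) + runif(1, 0, 50)
      expect_gte(compute_fsam_nps(q)$total_score, base)
    }
    q <- p
    q$fibre_g <- q$fibre_g + runif(1, 0, 4)
    expect_lte(compute_fsam_nps(q)$total_score, base)
  }
})

test_that("grade boundaries sit at 0, 2, 10 and 18", {
  scores <- -17:55
  grades <- grade_from_score(scores)
  changes <- scores[which(grades[-1] != grades[-length(grades)])]
  expect_equal(changes, c(0, 2, 10, 18))
  expect_equal(grade_from_score(c(0, 11, 55)), c("A", "D", "E"))
  expect_error(grade_from_score(56), "out of range")
})
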