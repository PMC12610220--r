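test_that("label values parse with upper bounds, decimal commas and units", {
  expect_equal(parse_label_value("<0.5 g"), list(value = 0.5, upper_bound = TRUE))
  expect_equal(parse_label_value("0,9"), list(value = 0.9, upper_bound = FALSE))
  expect_equal(parse_label_value("12.41"), list(value = 12.41, upper_bound = FALSE))
  expect_equal(parse_label_value("< 1,2 mg")$value, 1.2)
  expect_error(parse_label_value("n/a"), "n/a")
  expect_error(parse_label_value(""), "empty")
})

test_that("energy conversion uses 4.184 kJ/kcal and round-trips", {
  expect_equal(round(kcal_from_kj(1142)), 273)
  expect_equal(kcal_from_kj(0), 0)
  expect_equal(kcal_from_kj(4.184), 1)
  expect_error(kcal_from_kj(-1), "non-negative")
  x <- c(0.1, 1, 97.3, 1142, 3350)
  expect_equal(kcal_from_kj(kj_from_kcal(x)), x, tolerance = 1e-12)
})

test_that("fibre imputation from energy differences clamps and flags", {
  imp <- estimate_fibre_from_energy(500, 5, 10, 5)
  expect_equal(imp$fibre_g, 7.5)
  expect_true(imp$reliable)
  # zero residual
  expect_equal(estimate_fibre_from_energy(37 * 5 + 17 * 10 + 17 * 5,
                                          5, 10, 5)$fibre_g, 0)
  # negative residual clamps to 0, unreliable
  low <- estimate_fibre_from_energy(100, 5, 10, 5)
  expect_equal(low$fibre_g, 0)
  expect_false(low$reliable)
  # implausibly high fibre relative to carbohydrate is unreliable
  high <- estimate_fibre_from_energy(1000, 1, 2, 3)
  expect_false(high$reliable)
  expect_error(estimate_fibre_from_energy(NA, 5, 10, 5), "cannot impute")
})

test_that("fibre imputation inverts energy synthesis", {
  set.seed(7)
  for (i in 1:50) {
    fat <- runif(1, 0, 30); cho <- runif(1, 0, 30)
    protein <- runif(1, 0, 30); fibre <- runif(1, 0, min(cho + 2, 10))
    e <- 37 * fat + 17 * cho + 17 * protein + 8 * fibre
    imp <- estimate_fibre_from_energy(e, fat, cho, protein)
    expect_equal(imp$fibre_g, fibre, tolerance = 1e-9)
    expect_true(imp$reliable)
  }
})

test_that("protein energy share and claim threshold behave as specified", {
  expect_equal(round(protein_energy_percent(20.86, kj_from_kcal(272.50))), 31)
  expect_equal(protein_energy_percent(0, 500), 0)
  expect_equal(protein_energy_percent(10, 17 * 10), 100)
  expect_error(protein_energy_percent(10, 0), "energy_kj > 0")
  # boundary is inclusive: exactly 12% qualifies
  expect_true(protein_claim_eligible(12, 17 * 12 / 0.12))
  expect_true(protein_claim_eligible(20.86, kj_from_kcal(272.50)))
  expect_false(protein_claim_eligible(0, 500))
})

test_that("products CSV reads, imputes fibre, and rejects invalid rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(fixture_csv_text(), path)
  prod <- read_products_csv(path)
  expect_equal(nrow(prod), 3)
  expect_equal(prod$satfat_g[1], 0.5)
  expect_equal(prod$upper_bound_nutrients[1], "satfat_g")
  expect_equal(prod$sugar_g[1], 1.5)
  expect_equal(prod$fibre_status, c("declared", "declared", "imputed"))
  expect_equal(prod$fibre_g[3],
               estimate_fibre_from_energy(1044.3, 13.01, 18.33, 12.49)$fibre_g)
  # empty modifier flags take per-subcategory defaults on the animal arm
  expect_true(prod$red_meat_derived[2])
  expect_false(prod$red_meat_derived[1])

  bad <- product_row(satfat = 12, fat = 10)
  expect_error(validate_products(bad), "rows 1.*saturated fat exceeds fat")
  bad2 <- product_row(subcategory = "salami")
  bad2$main_category <- "meat"
  expect_error(validate_products(bad2), "inconsistent with main_category")
  bad3 <- product_row(arm = "plant", red_meat = TRUE)
  expect_error(validate_products(bad3), "red_meat_derived")
})

test_that("write then read is the identity on all fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(fixture_csv_text(), path)
  prod <- read_products_csv(path)
  out <- withr::local_tempfile(fileext = ".csv")
  write_products_csv(prod, out)
  again <- read_products_csv(out)
  expect_equal(again, prod)

  # also on a generated cohort (no upper bounds, declared fibre)
  cohort <- generate_cohort(small_config(), seed = 3)
  out2 <- withr::local_tempfile(fileext = ".csv")
  write_products_csv(cohort, out2)
  expect_equal(read_products_csv(out2), cohort)
})
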