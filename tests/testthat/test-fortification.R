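test_that("NRV coverage is linear and anchored at the reference values", {
  expect_equal(nrv_coverage("vitamin_b12", 1.3), 32.5)
  expect_equal(nrv_coverage("vitamin_b12", 0.38), 9.5)
  expect_equal(nrv_coverage("iron", 0), 0)
  nrv <- default_nrv_table()
  for (i in seq_len(nrow(nrv))) {
    expect_equal(nrv_coverage(nrv$nutrient[i], nrv$nrv[i], nrv), 100)
  }
  amounts <- c(0.5, 1, 2)
  expect_equal(nrv_coverage("zinc", 2 * amounts),
               2 * nrv_coverage("zinc", amounts))
  expect_error(nrv_coverage("selenium", 1), "no NRV entry")
  expect_error(nrv_coverage("iron", -1), "non-negative")
})

test_that("fortificant declarations parse and convert units", {
  f <- parse_fortificants("vitamin_b12=1.0ug;iron=2.1mg")
  expect_equal(f$nutrient, c("vitamin_b12", "iron"))
  expect_equal(f$amount, c(1.0, 2.1))
  expect_equal(parse_fortificants("")$nutrient, character(0))
  expect_equal(parse_fortificants("iron")$amount, NA_real_)

  prod <- rbind(
    product_row("f1", fortificants = "vitamin_b12=1.3ug;iron=2.1mg",
                ingredients = "water, soy protein concentrate, iron, vitamin b12"),
    product_row("f2", fortificants = "iron=3.5mg",
                ingredients = "water, soy protein concentrate"),
    product_row("f3", fortificants = "")
  )
  rec <- fortification_records(prod)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$nrv_coverage_percent[rec$product_id == "f1" &
                                          rec$nutrient == "vitamin_b12"], 32.5)
  # iron declared but absent from the ingredient list: naturally occurring
  expect_false(rec$declared_as_added[rec$product_id == "f2"])
  expect_true(all(rec$declared_as_added[rec$product_id == "f1"]))
})

test_that("additive annotation applies the paprika and flavouring rules", {
  a <- classify_additives("colouring paprika extract")
  expect_equal(a$functional_class, "colorant")
  expect_true(a$counted)
  b <- classify_additives("paprika extract")
  expect_false(b$counted)
  expect_match(b$note, "exempt")
  c <- classify_additives("methylcellulose")
  expect_equal(c$token, "methylcellulose")
  expect_equal(c$functional_class, "thickener")
  expect_true(c$counted)
  # flavourings are flagged but never counted as additives
  d <- classify_additives("water, natural flavouring, salt")
  expect_true(d$is_flavouring)
  expect_false(d$counted)
  # E-numbers resolve to the same entries as names
  e <- classify_additives("stabiliser E461, thickener e 415")
  expect_setequal(e$token, c("methylcellulose", "xanthan gum"))
})

test_that("additive counting is idempotent over duplicate mentions", {
  a <- classify_additives(
    "methylcellulose, spices, methylcellulose, xanthan gum, E461")
  expect_equal(sum(a$token == "methylcellulose"), 1)
  expect_equal(sum(a$counted), 2)
})

test_that("additive summary equals a brute-force recount", {
  prod <- rbind(
    product_row("a1", ingredients = "water, soy protein concentrate"),
    product_row("a2", ingredients = "water, methylcellulose, xanthan gum, natural flavouring"),
    product_row("a3", ingredients = "methylcellulose, carrageenan, citric acid, beetroot red"),
    product_row("a4", arm = "animal", ingredients = "")
  )
  s <- additive_summary(prod)
  expect_equal(s$per_product$n_additives, c(0, 2, 4))
  expect_equal(s$by_subcategory$mean_additives, 2)
  expect_equal(s$by_subcategory$share_additive_free, 1 / 3)
  expect_equal(s$by_subcategory$flavouring_share, 1 / 3)

  cohort <- generate_cohort(small_config(), seed = 21)
  cs <- additive_summary(cohort)
  recount <- vapply(cohort$ingredients_text[cohort$arm == "plant"],
                    function(t) sum(classify_additives(t)$counted),
                    integer(1))
  expect_equal(cs$per_product$n_additives, unname(recount))
})
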