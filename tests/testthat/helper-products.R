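# Shared fixture builders: everything is constructed in code at test time.

# one fully specified product row in the in-memory schema
product_row <- function(product_id = "p1", arm = "plant",
                        subcategory = "minced_meat",
                        energy_kcal = 200, fat = 10, satfat = 2, cho = 6,
                        sugar = 1, fibre = 4, protein = 15, salt = 1.5,
                        ingredients = "water, soy protein concentrate, salt",
                        fortificants = "",
                        red_meat = NULL, salt_added = NULL) {
  tab <- subcategory_table()
  mc <- tab$main_category[match(subcategory, tab$subcategory)]
  flags <- default_modifier_flags(arm, subcategory)
  data.frame(
    product_id = product_id, name = paste("test", product_id),
    brand = "testbrand", arm = arm, main_category = mc,
    subcategory = subcategory,
    energy_kj = kj_from_kcal(energy_kcal), energy_kcal = energy_kcal,
    fat_g = fat, satfat_g = satfat, cho_g = cho, sugar_g = sugar,
    fibre_g = fibre, protein_g = protein, salt_g = salt,
    fibre_status = "declared", fibre_reliable = TRUE,
    upper_bound_nutrients = "",
    ingredients_text = ingredients, fortificants = fortificants,
    red_meat_derived = red_meat %||% flags$red_meat_derived,
    salt_added_in_prep = salt_added %||% flags$salt_added_in_prep,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small two-arm cohort built from the default configuration, capped counts
small_config <- function(subcats = c("minced_meat", "cooked_sausage"),
                         n_cap = 12) {
  cfg <- default_config_from_table2()
  cfg$cells <- cfg$cells[cfg$cells$subcategory %in% subcats, , drop = FALSE]
  cfg$cells$n <- pmin(cfg$cells$n, n_cap)
  cfg
}

# text of a minimal valid products CSV (3 rows), exercising decimal commas,
# "<x" upper bounds and an empty fibre cell
fixture_csv_text <- function() {
  c(paste("product_id,name,brand,arm,main_category,subcategory,energy_kj,",
          "energy_kcal,fat_g,satfat_g,cho_g,sugar_g,fibre_g,protein_g,",
          "salt_g,ingredients_text,fortificants,red_meat_derived,",
          "salt_added_in_prep", sep = ""),
    'c1,Burger,BrandA,plant,meat,minced_meat,861.1,205.8,12.4,"<0,5",6.4,"1,5",4.9,14.6,1.61,"water, soy protein concentrate, methylcellulose",,false,false',
    "c2,Mince,BrandB,animal,meat,minced_meat,1028.1,245.7,18.02,7.53,3.18,0.56,0.16,17.86,1.18,,,true,true",
    "c3,Schnitzel,BrandC,plant,meat,breaded_meat,1044.3,249.6,13.01,1.37,18.33,1.06,,12.49,1.35,\"water, wheat gluten, pea protein isolate\",vitamin_b12=1.3ug,false,false")
}

# exact two-sided Mann-Whitney p by enumerating all group labelings of the
# pooled sample (independent oracle, midranks for ties)
mw_exact_oracle <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  mu <- nx * length(y) / 2
  obs <- abs(sum(r[seq_len(nx)]) - nx * (nx + 1) / 2 - mu)
  combos <- utils::combn(n, nx)
  devs <- apply(combos, 2, function(idx) {
    abs(sum(r[idx]) - nx * (nx + 1) / 2 - mu)
  })
  mean(devs >= obs - 1e-9)
}
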