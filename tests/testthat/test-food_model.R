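test_that("collapse_fct averages item matches and flags zero-imputed cells", {
  m <- tibble::tibble(
    fc_code = c("beef", "beef", "milk"),
    iron_mg = c(2, 4, 0.1),
    vitamin_d_mcg = c(1, NA, 0.5)
  )
  out <- collapse_fct(m)
  expect_equal(out$iron_mg[out$fc_code == "beef"], 3)
  expect_equal(out$n_source_items, c(2, 1))
  # missing value enters the mean at its lower bound of zero, and is flagged
  expect_equal(out$vitamin_d_mcg[out$fc_code == "beef"], 0.5)
  expect_equal(imputed_cells(out),
               tibble::tibble(fc_code = "beef", nutrient = "vitamin_d_mcg"))

  # single match is the identity
  one <- collapse_fct(tibble::tibble(fc_code = "tea", iron_mg = 1.1))
  expect_equal(one$iron_mg, 1.1)
  expect_equal(one$n_source_items, 1)

  expect_error(collapse_fct(m[0, ]), "no composition")
  expect_error(collapse_fct(tibble::tibble(fc_code = "x", iron_mg = -1)), ">= 0")
})

test_that("collapse_fct is idempotent and permutation-invariant", {
  set.seed(1)
  m <- tibble::tibble(
    fc_code = sample(rep(c("a", "b", "c"), each = 4)),
    energy_kcal = runif(12, 50, 300),
    iron_mg = runif(12, 0, 5)
  )
  once <- collapse_fct(m)
  twice <- collapse_fct(once |> dplyr::select(-"n_source_items"))
  expect_equal(twice$energy_kcal, once$energy_kcal)
  expect_equal(twice$iron_mg, once$iron_mg)

  shuffled <- collapse_fct(m[sample(nrow(m)), ])
  expect_equal(shuffled |> dplyr::arrange(fc_code),
               once |> dplyr::arrange(fc_code), ignore_attr = TRUE)
})

test_that("resolve_composition applies blend and replace overrides", {
  fct <- tibble::tibble(
    fc_code = c("palm_oil", "palm_oil_red", "rice", "rice_parboiled", "beans"),
    vitamin_a_mcg = c(0, 5000, 0, 0, 10),
    iron_mg = c(0.1, 0.2, 1, 1.2, 5)
  )
  rules <- list(
    list(type = "blend", fc_code = "palm_oil", blend_fc = "palm_oil_red",
         blend_share = 0.7, countries = c("NGA", "GHA")),
    list(type = "replace", fc_code = "rice", replacement_fc = "rice_parboiled",
         countries = "BGD")
  )
  # domestic retention blends 70% red palm oil: 0.7*5000 + 0.3*0
  dom <- resolve_composition(fct, "palm_oil", "NGA", "domestic_retained", rules)
  expect_equal(dom[["vitamin_a_mcg"]], 3500)
  # exports and imports stay refined
  expect_equal(resolve_composition(fct, "palm_oil", "NGA", "export", rules)[["vitamin_a_mcg"]], 0)
  expect_equal(resolve_composition(fct, "palm_oil", "NGA", "import", rules)[["vitamin_a_mcg"]], 0)
  # non-listed country: base record
  expect_equal(resolve_composition(fct, "palm_oil", "FRA", "domestic_retained", rules)[["vitamin_a_mcg"]], 0)
  # replacement fires for all flow roles
  expect_equal(resolve_composition(fct, "rice", "BGD", "import", rules)[["iron_mg"]], 1.2)
  # non-override pair equals plain table lookup
  expect_equal(resolve_composition(fct, "beans", "BGD", "domestic_retained", rules),
               c(vitamin_a_mcg = 10, iron_mg = 5))
  expect_true(all(dom >= 0))

  expect_error(resolve_composition(fct, "nope", "NGA", "export"), "unknown food category")
  expect_error(resolve_composition(fct, "beans", NA_character_, "export"), "unknown country")
})

test_that("default shipped rules parse and name real override targets", {
  rules <- composition_rules()
  expect_length(rules, 2)
  types <- vapply(rules, `[[`, "", "type")
  expect_setequal(types, c("blend", "replace"))
  blend <- rules[[which(types == "blend")]]
  expect_equal(blend$blend_share, 0.7)
  expect_true("NGA" %in% blend$countries)
})

test_that("validate_taxonomy reports structural defects and passes clean input", {
  tax <- test_world()$taxonomy
  expect_equal(nrow(validate_taxonomy(tax)), 0)

  broken <- dplyr::bind_rows(
    tax,
    tax[1, ],                                               # duplicate fc
    tibble::tibble(fc_code = "mystery", fsg_code = "fruits",
                   fg_code = NA_character_, is_fco = FALSE, is_hsi = FALSE),
    tibble::tibble(fc_code = "odd_fruit", fsg_code = "fruits",
                   fg_code = "nutrient_dense_vegetal", is_fco = FALSE,
                   is_hsi = TRUE)                           # heme flag on a fruit
  )
  broken$is_fco[broken$fc_code == "bananas"] <- TRUE        # second FCO? no: first in fruits
  report <- validate_taxonomy(broken)
  expect_true("duplicate_fc" %in% report$check)
  expect_true("fc_without_valid_fg" %in% report$check)
  expect_true("hsi_outside_animal_source" %in% report$check)

  two_fco <- tax
  two_fco$is_fco[two_fco$fsg_code == "cereals"] <- TRUE
  expect_true("fsg_multiple_fco" %in% validate_taxonomy(two_fco)$check)
})
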