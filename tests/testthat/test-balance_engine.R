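test_that("to_per_capita converts 1000 MT/yr to g/person/day over a 365-day year", {
  expect_equal(to_per_capita(36.5, 1e6), 100)
  expect_equal(to_per_capita(0, 5e7), 0)
  expect_error(to_per_capita(1, 0), "positive")
  expect_error(to_per_capita(1, -10), "positive")
})

test_that("split_cereal_flours applies milling extraction to each stream", {
  s <- split_cereal_flours(100, 0.8, 0.72, 1.0)
  expect_equal(s$refined, 57.6)
  expect_equal(s$whole, 20)
  expect_equal(split_cereal_flours(100, 0, 0.72, 1.0),
               list(refined = 0, whole = 100))
  expect_equal(split_cereal_flours(100, 1, 0.70, 1.0)$refined, 70)
  expect_error(split_cereal_flours(100, 1.2, 0.7, 1), "\\[0, 1\\]")
  expect_error(split_cereal_flours(100, 0.5, 0, 1), "\\(0, 1\\]")
})

test_that("flour split conserves pre-extraction grain mass", {
  for (p in c(0, 0.3, 0.8, 1)) {
    s <- split_cereal_flours(250, p, 0.72, 1.0)
    expect_equal(s$refined / 0.72 + s$whole / 1.0, 250)
  }
})

test_that("processing factors scale to the as-consumed form", {
  expect_equal(apply_processing_factor(10, 0.11), 1.1)
  expect_equal(apply_processing_factor(1, 119.05), 119.05)
  expect_equal(apply_processing_factor(7, 1), 7)
  expect_error(apply_processing_factor(1, 0), "> 0")
})

test_that("compute_nutrients follows the accounting identity per variant", {
  # beef-style example: 200 g/day at 33.3% refuse, iron 2.0 mg/100 g
  expect_equal(
    compute_nutrients(200, c(iron_mg = 2), refuse_fraction = 0.333,
                      variant = "processing_only")[["iron_mg"]],
    2.668
  )
  fb <- compute_nutrients(200, c(iron_mg = 2), refuse_fraction = 0.333,
                          flw = c(postharvest = 0, retail = 0.05, consumption = 0.11),
                          cooking_retention = c(iron_mg = 0.90),
                          variant = "final_best")
  expect_equal(fb[["iron_mg"]], 2.668 * 0.95 * 0.89 * 0.90)

  # exempt subgroup: zero FLW fractions leave only the cooking loss
  ex <- compute_nutrients(50, c(vitamin_a_mcg = 100), processing_retention = 0.9,
                          flw = c(postharvest = 0, retail = 0, consumption = 0),
                          cooking_retention = c(vitamin_a_mcg = 0.8),
                          variant = "final_best")
  po <- compute_nutrients(50, c(vitamin_a_mcg = 100), processing_retention = 0.9,
                          variant = "processing_only")
  expect_equal(ex[["vitamin_a_mcg"]], po[["vitamin_a_mcg"]] * 0.8)

  # raw ignores the processing retention
  expect_equal(
    compute_nutrients(50, c(energy_kcal = 100), processing_retention = 0.5,
                      variant = "raw")[["energy_kcal"]],
    50
  )
  expect_error(compute_nutrients(-1, c(a = 1)), ">= 0")
  expect_error(compute_nutrients(1, c(a = 1), refuse_fraction = 1), "refuse")
})

test_that("compute_nutrients is homogeneous of degree 1 in quantity and
           final_best never exceeds processing_only", {
  set.seed(3)
  for (i in 1:25) {
    g <- runif(1, 0, 500)
    comp <- c(energy_kcal = runif(1, 10, 400), iron_mg = runif(1, 0, 6))
    refuse <- runif(1, 0, 0.5)
    proc <- runif(1, 0.1, 1.2)
    flw <- c(postharvest = runif(1, 0, 0.2), retail = runif(1, 0, 0.2),
             consumption = runif(1, 0, 0.2))
    cook <- c(energy_kcal = runif(1, 0.5, 1), iron_mg = runif(1, 0.5, 1))
    k <- runif(1, 0.1, 10)
    for (v in c("raw", "processing_only", "flw_cooking_only", "final_best")) {
      expect_equal(
        compute_nutrients(k * g, comp, refuse, proc, flw, cook, v),
        k * compute_nutrients(g, comp, refuse, proc, flw, cook, v)
      )
    }
    expect_true(all(
      compute_nutrients(g, comp, refuse, proc, flw, cook, "final_best") <=
        compute_nutrients(g, comp, refuse, proc, flw, cook, "processing_only") + 1e-12
    ))
  }
})

test_that("aggregate_country excludes processed foods from production only", {
  nf <- tibble::tibble(
    country = "X", year = 2000,
    fc_code = rep(c("wheat", "palm_oil"), each = 2),
    form = "primary",
    element = rep(c("production", "food"), 2),
    nutrient = "energy_kcal",
    value = c(10, 8, 5, 4)
  )
  tax <- tibble::tibble(fc_code = c("wheat", "palm_oil"),
                        exclude_from_production = c(FALSE, TRUE))
  prod <- aggregate_country(nf, tax, "production")
  expect_equal(prod$value, 10)              # palm oil production not counted
  intake <- aggregate_country(nf, tax, "apparent_intake")
  expect_equal(intake$value, 12)            # both food flows counted

  # degenerate country-year with no food element at all -> zero with warning
  nf2 <- dplyr::bind_rows(nf, tibble::tibble(
    country = "Y", year = 2000, fc_code = "wheat", form = "primary",
    element = "production", nutrient = "energy_kcal", value = 3))
  expect_warning(out <- aggregate_country(nf2, tax, "apparent_intake"),
                 "filled with zero")
  expect_equal(out$value[out$country == "Y"], 0)
})

test_that("cereal split, processing factors and overrides flow through the
           table engine exactly as the scalar operations prescribe", {
  w <- test_world()
  nf <- compute_nutrient_flows(w, "processing_only")

  # wheat in a region with an 0.8/0.72 split: refined + whole forms present
  wheat <- nf$mass |>
    dplyr::filter(fc_code == "wheat", country == "CA", year == w$spec$years[1],
                  element == "food")
  expect_setequal(wheat$form, c("refined", "whole"))
  split_spec <- w$cereal_splits[w$cereal_splits$fc_code == "wheat" &
                                  w$cereal_splits$region == "R1", ]
  grain_g <- to_per_capita(
    w$flows$qty_1000mt[w$flows$country == "CA" & w$flows$year == w$spec$years[1] &
                         w$flows$fc_code == "wheat" & w$flows$element == "food"],
    w$populations$population[w$populations$country == "CA" &
                               w$populations$year == w$spec$years[1]]
  )
  manual <- split_cereal_flours(grain_g, split_spec$refined_proportion,
                                split_spec$refined_extraction,
                                split_spec$whole_extraction)
  expect_equal(wheat$g_day[wheat$form == "refined"], manual$refined)
  expect_equal(wheat$g_day[wheat$form == "whole"], manual$whole)

  # tea mass is diluted by its brewing factor in processing variants only
  raw <- compute_nutrient_flows(w, "raw")
  tea_raw <- raw$mass |> dplyr::filter(fc_code == "tea", element == "food")
  tea_proc <- nf$mass |> dplyr::filter(fc_code == "tea", element == "food")
  expect_equal(tea_proc$g_day, tea_raw$g_day * 119.05)
})
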