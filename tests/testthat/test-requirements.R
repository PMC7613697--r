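test_that("pregnancy estimation is duration-weighted and linear", {
  expect_equal(estimate_pregnant(0, 0, 0), 0)
  expect_equal(estimate_pregnant(1000, 0, 0,
                                 c(birth = 0.75, abortion = 0.2, miscarriage = 0.2)),
               750)
  d <- c(birth = 40 / 52, abortion = 10 / 52, miscarriage = 10 / 52)
  expect_equal(estimate_pregnant(1000, 100, 50, d),
               1000 * 40 / 52 + 100 * 10 / 52 + 50 * 10 / 52)
  expect_equal(estimate_pregnant(2000, 200, 100, d),
               2 * estimate_pregnant(1000, 100, 50, d))
  expect_error(estimate_pregnant(-1), ">= 0")
})

test_that("lactation runs six months per birth, infants 0-5 mo track it", {
  l <- estimate_lactating(1e6)
  expect_equal(l$lactating, 5e5)
  expect_equal(l$infants_0_5, l$lactating)
  expect_equal(estimate_lactating(0)$lactating, 0)
  expect_equal(estimate_lactating(1000, exclusive_bf_fraction = 0.6)$infants_0_5, 300)
})

test_that("reproductive reallocation conserves total persons", {
  cells <- tidyr::expand_grid(age = 0:60, sex = c("f", "m")) |>
    dplyr::mutate(count = 100)
  out <- reallocate_reproductive(cells, pregnant_n = 150, lactating_n = 250)
  expect_equal(sum(out$count), sum(cells$count))
  expect_equal(out$count[out$pregnant], 150)
  expect_equal(out$count[out$lactating], 250)
  # only eligible female cells were shrunk
  shrunk <- out |> dplyr::filter(!pregnant, !lactating)
  male <- shrunk |> dplyr::filter(sex == "m")
  expect_true(all(male$count == 100))
  expect_error(reallocate_reproductive(cells, 1e6, 1e6), "exceed")
})

simple_drvs <- tibble::tribble(
  ~nutrient, ~sex, ~age_min, ~age_max, ~pregnant, ~lactating, ~value_type, ~value, ~basis,
  "vitamin_a_mcg", "any", 0L, 17L, FALSE, FALSE, "AR", 700, "absolute_per_day",
  "vitamin_a_mcg", "any", 18L, 150L, FALSE, FALSE, "AR", 900, "absolute_per_day",
  "protein_g", "any", 0L, 150L, FALSE, FALSE, "AR", 1.0, "per_kg_bodyweight"
)

test_that("weighted requirements are population-weighted means of group DRVs", {
  one <- tibble::tibble(age = 30, sex = "f", count = 50,
                        pregnant = FALSE, lactating = FALSE)
  expect_equal(weighted_requirement(one, simple_drvs, "vitamin_a_mcg")$requirement, 900)

  cells <- tibble::tibble(age = c(10, 30), sex = "f", count = c(100, 300),
                          pregnant = FALSE, lactating = FALSE)
  wr <- weighted_requirement(cells, simple_drvs, "vitamin_a_mcg")
  expect_equal(wr$requirement, (100 * 700 + 300 * 900) / 400)
  expect_equal(wr$standard_used, "AR")

  bw <- tibble::tibble(sex = "any", age_min = 0L, age_max = 150L, weight_kg = 70)
  pr <- weighted_requirement(one, simple_drvs, "protein_g", body_weights = bw)
  expect_equal(pr$requirement, 70)  # 1.0 g/kg * 70 kg

  # requirement bounded by the group DRVs
  expect_gte(wr$requirement, 700)
  expect_lte(wr$requirement, 900)

  # splitting a cell within one DRV group changes nothing
  split_cells <- tibble::tibble(age = c(10, 11, 30), sex = "f",
                                count = c(60, 40, 300),
                                pregnant = FALSE, lactating = FALSE)
  expect_equal(weighted_requirement(split_cells, simple_drvs, "vitamin_a_mcg")$requirement,
               wr$requirement)

  expect_error(weighted_requirement(one, simple_drvs, "zinc_mg"), "no DRVs")
  bad <- tibble::tibble(age = 200, sex = "f", count = 1,
                        pregnant = FALSE, lactating = FALSE)
  expect_error(
    weighted_requirement(bad, simple_drvs[1, ], "vitamin_a_mcg"),
    "no DRV group"
  )
})

test_that("the AR-else-AI preference picks the available standard", {
  drvs <- dplyr::bind_rows(
    simple_drvs,
    tibble::tibble(nutrient = "vitamin_c_mg", sex = "any", age_min = 0L,
                   age_max = 150L, pregnant = FALSE, lactating = FALSE,
                   value_type = "AI", value = 80, basis = "absolute_per_day")
  )
  one <- tibble::tibble(age = 30, sex = "m", count = 10,
                        pregnant = FALSE, lactating = FALSE)
  out <- weighted_requirement(one, drvs, "vitamin_c_mg")
  expect_equal(out$standard_used, "AI")
  expect_equal(out$requirement, 80)
})

test_that("the NNRD matches the generator's independent weighting, conserves
           persons, and carries absorbed-basis rows for iron and zinc", {
  w <- test_world()
  res <- test_pipeline()
  gt <- w$ground_truth$nnrd |> dplyr::arrange(country, year, nutrient, standard_used)
  got <- res$nnrd |> dplyr::arrange(country, year, nutrient, standard_used)
  expect_equal(nrow(got), nrow(gt))
  expect_lt(max_rel_err(got$requirement, gt$requirement), 1e-9)
  expect_setequal(
    got$standard_used[got$nutrient == "iron_mg"], c("AR", "physiological"))
  expect_setequal(
    unique(got$standard_used[got$nutrient == "vitamin_c_mg"]), "AI")
})
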