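#' Specification for a synthetic food-system world
#'
#' Defines the shape of a generated test world: structurally faithful to
#' national commodity-flow accounts (food categories nested in subgroups
#' with catch-all "other" categories, milling splits for wheat and maize,
#' processing factors for tea and sugar cane, exempt subgroups for loss and
#' waste, heme-iron sources, demographic pyramids with pregnancy and
#' lactation) but not calibrated to real-world magnitudes.
#'
#' @param n_countries Number of countries (2-26).
#' @param years Integer vector of years.
#' @param seed Integer seed; the generated bundle is deterministic given the
#'   seed.
#' @param fco_flow_fraction Fraction of national food-element mass routed to
#'   catch-all categories.
#' @param target_adequacy Optional tibble (`country`, `nutrient`,
#'   `percent_gap`) requesting that a country's apparent intake land at a
#'   given percent gap from requirement for one nutrient (achieved by
#'   rescaling that country's food flows; at most one nutrient per country).
#' @return A `world_spec` list.
#' @export
world_spec <- function(n_countries = 3, years = c(2000, 2001), seed = 1,
                       fco_flow_fraction = 0.15, target_adequacy = NULL) {
  stopifnot(n_countries >= 2, n_countries <= 26, length(years) >= 1)
  structure(list(n_countries = n_countries, years = as.integer(years),
                 seed = as.integer(seed),
                 fco_flow_fraction = fco_flow_fraction,
                 target_adequacy = target_adequacy),
            class = "world_spec")
}

world_taxonomy <- function() {
  tibble::tribble(
    ~fc_code,           ~name,               ~fsg_code,    ~fg_code,                 ~is_fco, ~is_fv, ~is_hsi, ~is_mfp, ~exclude_from_production, ~cereal,
    "wheat",            "Wheat and products", "cereals",    "starchy_staples",        FALSE,  FALSE,  FALSE,   FALSE,   FALSE,                    "wheat",
    "maize",            "Maize and products", "cereals",    "starchy_staples",        FALSE,  FALSE,  FALSE,   FALSE,   FALSE,                    "maize",
    "rice",             "Rice and products",  "cereals",    "starchy_staples",        FALSE,  FALSE,  FALSE,   FALSE,   FALSE,                    NA,
    "cereals_other",    "Cereals, other",     "cereals",    "starchy_staples",        TRUE,   FALSE,  FALSE,   FALSE,   FALSE,                    NA,
    "tomatoes",         "Tomatoes",           "vegetables", "nutrient_dense_vegetal", FALSE,  TRUE,   FALSE,   FALSE,   FALSE,                    NA,
    "vegetables_other", "Vegetables, other",  "vegetables", "nutrient_dense_vegetal", TRUE,   TRUE,   FALSE,   FALSE,   FALSE,                    NA,
    "bananas",          "Bananas",            "fruits",     "nutrient_dense_vegetal", FALSE,  TRUE,   FALSE,   FALSE,   FALSE,                    NA,
    "pulses_other",     "Pulses, other",      "pulses",     "nutrient_dense_vegetal", TRUE,   FALSE,  FALSE,   FALSE,   FALSE,                    NA,
    "beef",             "Bovine meat",        "meat",       "animal_source",          FALSE,  FALSE,  TRUE,    TRUE,    FALSE,                    NA,
    "poultry",          "Poultry meat",       "meat",       "animal_source",          FALSE,  FALSE,  TRUE,    TRUE,    FALSE,                    NA,
    "fish_pelagic",     "Pelagic fish",       "fish",       "animal_source",          FALSE,  FALSE,  TRUE,    TRUE,    FALSE,                    NA,
    "milk",             "Milk",               "dairy",      "animal_source",          FALSE,  FALSE,  FALSE,   FALSE,   FALSE,                    NA,
    "palm_oil",         "Palm oil",           "oils",       "other",                  FALSE,  FALSE,  FALSE,   FALSE,   TRUE,                     NA,
    "tea",              "Tea",                "stimulants", "other",                  FALSE,  FALSE,  FALSE,   FALSE,   FALSE,                    NA,
    "sugar_cane",       "Sugar cane",         "sugar",      "other",                  FALSE,  FALSE,  FALSE,   FALSE,   FALSE,                    NA
  ) |>
    dplyr::mutate(cpc_codes = sprintf("CPC%04d;CPC%04d",
                                      100 + dplyr::row_number(),
                                      200 + dplyr::row_number()))
}

world_nutrient_ranges <- function() {
  # per-100g sampling ranges by nutrient (edible portion)
  list(
    energy_kcal = c(40, 400), protein_g = c(0.5, 25), fat_g = c(0.1, 20),
    vitamin_a_mcg = c(0, 120), vitamin_c_mg = c(0, 60), iron_mg = c(0.3, 5),
    zinc_mg = c(0.2, 4), calcium_mg = c(5, 150), phytate_mg = c(0, 0),
    polyphenol_mg = c(0, 0)
  )
}

#' Generate a synthetic food-system world with construction-time ground truth
#'
#' Builds every input table the pipeline consumes (flows, composition,
#' refuse, processing factors, milling splits, loss & waste, cooking
#' retention, demographics, reproductive statistics, reference values, body
#' weights, catch-all candidate sets, override rules) and computes the
#' expected outputs — per-capita nutrient totals under all four
#' loss-accounting variants, diet profiles, bioavailable minerals, weighted
#' requirements, adequacy and a worked deficit summary — by direct formula
#' evaluation in a code path separate from the engine, so the bundle can
#' serve as an end-to-end oracle.
#'
#' @param spec A [world_spec()].
#' @return A list of input tibbles plus `ground_truth` and the originating
#'   `spec`.
#' @export
generate_world <- function(spec = world_spec()) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(spec$seed)
  taxonomy <- world_taxonomy()
  countries <- tibble::tibble(
    country = paste0("C", LETTERS[seq_len(spec$n_countries)]),
    region = rep(c("R1", "R2"), length.out = spec$n_countries)
  )

  ## --- composition -------------------------------------------------------
  rng <- world_nutrient_ranges()
  nut <- names(rng)
  draw_comp <- function(n) {
    vapply(nut, function(k) stats::runif(n, rng[[k]][1], rng[[k]][2]),
           numeric(n))
  }
  fct <- tibble::as_tibble(draw_comp(nrow(taxonomy)))
  fct$fc_code <- taxonomy$fc_code
  # domain structure: phytate in cereals & pulses, polyphenols in tea,
  # carotenoid-rich red palm oil, energy always positive
  cereal_like <- taxonomy$fsg_code %in% c("cereals", "pulses")
  fct$phytate_mg[cereal_like] <- stats::runif(sum(cereal_like), 100, 800)
  fct$polyphenol_mg[fct$fc_code == "tea"] <- 95
  fct$vitamin_a_mcg[fct$fc_code == "palm_oil"] <- 0

  extra_codes <- c("wheat_refined", "wheat_whole", "maize_refined",
                   "maize_whole", "palm_oil_red", "rice_parboiled")
  extra <- tibble::as_tibble(draw_comp(length(extra_codes)))
  extra$fc_code <- extra_codes
  extra$phytate_mg <- c(stats::runif(4, 150, 700), 0, stats::runif(1, 100, 400))
  extra$polyphenol_mg <- 0
  extra$vitamin_a_mcg[extra$fc_code == "palm_oil_red"] <- 4500
  fct <- dplyr::bind_rows(fct, extra) |>
    dplyr::relocate("fc_code")

  ## --- catch-all candidate sets (FCT rows for FCOs = candidate means) ----
  fco_codes <- taxonomy$fc_code[taxonomy$is_fco]
  fco_candidates <- lapply(stats::setNames(fco_codes, fco_codes), function(fc) {
    m <- draw_comp(3)
    rownames(m) <- paste0(fc, "_item", 1:3)
    m
  })
  for (fc in fco_codes) {
    fct[fct$fc_code == fc, nut] <- as.list(colMeans(fco_candidates[[fc]]))
  }

  ## --- factor tables ------------------------------------------------------
  refuse <- tibble::tribble(
    ~fc_code, ~refuse_fraction,
    "beef", 0.333, "poultry", 0.29, "fish_pelagic", 0.45,
    "bananas", 0.36, "tomatoes", 0.09
  )
  processing_factors <- tibble::tribble(
    ~fc_code, ~factor,
    "tea", 119.05, "sugar_cane", 0.11
  )
  cereal_splits <- tibble::tribble(
    ~fc_code, ~region, ~refined_proportion, ~refined_extraction, ~whole_extraction,
    "wheat", "R1", 0.80, 0.72, 1.00,
    "wheat", "R2", 0.60, 0.72, 1.00,
    "maize", "R1", 0.50, 0.70, 1.00,
    "maize", "R2", 0.70, 0.70, 1.00
  )
  exempt_fsgs <- c("oils", "stimulants", "sugar")
  flw <- tidyr::expand_grid(region = unique(countries$region),
                            fsg_code = unique(taxonomy$fsg_code)) |>
    dplyr::mutate(
      exempt = .data$fsg_code %in% exempt_fsgs,
      postharvest = ifelse(.data$fsg_code == "fish" & !.data$exempt,
                           stats::runif(dplyr::n(), 0.04, 0.10), 0),
      retail = ifelse(.data$exempt, 0, stats::runif(dplyr::n(), 0.02, 0.08)),
      consumption = ifelse(.data$exempt, 0, stats::runif(dplyr::n(), 0.04, 0.15))
    )
  cooking <- tibble::tribble(
    ~fc_code, ~nutrient, ~retention,
    "tomatoes", "vitamin_c_mg", 0.60,
    "vegetables_other", "vitamin_c_mg", 0.65,
    "beef", "iron_mg", 0.90,
    "wheat_refined", "iron_mg", 0.95,
    "palm_oil", "vitamin_a_mcg", 0.80,
    "rice", "vitamin_c_mg", 0.50,
    "rice_parboiled", "vitamin_c_mg", 0.50
  )
  rules <- list(
    list(type = "blend", fc_code = "palm_oil", blend_fc = "palm_oil_red",
         blend_share = 0.70, countries = countries$country[1]),
    list(type = "replace", fc_code = "rice", replacement_fc = "rice_parboiled",
         countries = countries$country[2])
  )

  ## --- demographics -------------------------------------------------------
  ages <- 0:80
  demographics <- tidyr::expand_grid(country = countries$country,
                                     year = spec$years,
                                     age = ages, sex = c("f", "m")) |>
    dplyr::mutate(count = round(stats::runif(dplyr::n(), 5e3, 1.5e4) *
                                  exp(-.data$age / 90)))
  populations <- demographics |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::summarise(population = sum(.data$count), .groups = "drop")
  reproductive <- populations |>
    dplyr::mutate(live_births = round(.data$population * stats::runif(dplyr::n(), 0.015, 0.025)),
                  induced_abortions = round(.data$live_births * 0.12),
                  miscarriages = round(.data$live_births * 0.10)) |>
    dplyr::select(-"population")

  drvs <- world_drvs()
  body_weights <- world_body_weights()

  ## --- flows --------------------------------------------------------------
  elements <- c("production", "imports", "exports", "feed", "food")
  flows <- tidyr::expand_grid(country = countries$country, year = spec$years,
                              fc_code = taxonomy$fc_code, element = elements) |>
    dplyr::inner_join(populations, by = c("country", "year")) |>
    dplyr::mutate(
      scale = .data$population / 1e6,
      qty_1000mt = .data$scale * dplyr::case_match(.data$element,
        "production" ~ stats::runif(dplyr::n(), 20, 120),
        "imports" ~ stats::runif(dplyr::n(), 0, 30),
        "exports" ~ stats::runif(dplyr::n(), 0, 20),
        "feed" ~ stats::runif(dplyr::n(), 0, 10),
        "food" ~ stats::runif(dplyr::n(), 15, 90)
      )
    ) |>
    dplyr::select(-"population", -"scale")
  # tea/sugar food quantities are primary-commodity masses; keep them small
  flows <- flows |>
    dplyr::mutate(qty_1000mt = ifelse(.data$fc_code %in% c("tea", "sugar_cane"),
                                      .data$qty_1000mt * 0.05, .data$qty_1000mt))
  flows <- rescale_fco_share(flows, taxonomy, spec$fco_flow_fraction)

  world <- list(
    spec = spec, countries = countries, taxonomy = taxonomy, fct = fct,
    refuse = refuse, processing_factors = processing_factors,
    cereal_splits = cereal_splits, flw = flw, cooking = cooking,
    rules = rules, flows = flows, populations = populations,
    demographics = demographics, reproductive = reproductive,
    drvs = drvs, body_weights = body_weights,
    fco_candidates = fco_candidates,
    nutrients = nutrient_definitions()
  )

  ## --- adequacy targeting by flow rescaling -------------------------------
  if (!is.null(spec$target_adequacy)) {
    gt0 <- world_ground_truth(world)
    for (i in seq_len(nrow(spec$target_adequacy))) {
      tg <- spec$target_adequacy[i, ]
      for (yr in spec$years) {
        adeq <- gt0$adequacy
        row <- adeq[adeq$country == tg$country & adeq$year == yr &
                      adeq$nutrient == tg$nutrient, ]
        if (nrow(row) != 1L) stop("adequacy target refers to unknown cell", call. = FALSE)
        desired <- row$pc_requirement * (1 + tg$percent_gap / 100)
        if (desired < 0) stop("infeasible adequacy target (negative intake)", call. = FALSE)
        s <- desired / row$pc_value
        sel <- world$flows$country == tg$country & world$flows$year == yr &
          world$flows$element == "food"
        world$flows$qty_1000mt[sel] <- world$flows$qty_1000mt[sel] * s
      }
    }
  }

  world$ground_truth <- world_ground_truth(world)
  world
}

rescale_fco_share <- function(flows, taxonomy, frac) {
  fco <- taxonomy$fc_code[taxonomy$is_fco]
  flows |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::group_modify(function(df, key) {
      is_food <- df$element == "food"
      is_fco <- df$fc_code %in% fco & is_food
      f_mass <- sum(df$qty_1000mt[is_fco])
      o_mass <- sum(df$qty_1000mt[is_food & !df$fc_code %in% fco])
      if (f_mass > 0) {
        df$qty_1000mt[is_fco] <- df$qty_1000mt[is_fco] *
          (frac * o_mass / (1 - frac)) / f_mass
      }
      df
    }) |>
    dplyr::ungroup()
}

world_drvs <- function() {
  # synthetic reference values: four age bands, sex split from 15y, pregnancy
  # and lactation groups; vitamin C deliberately has only an AI so the
  # AR-else-AI fallback is exercised; iron and zinc carry both an ingested AR
  # and an absorbed-basis (physiological) standard; protein is per kg body
  # weight.
  band <- function(nutrient, type, basis, v0_3, v4_14, f15, m15, f50, m50,
                   preg, lact) {
    tibble::tribble(
      ~sex, ~age_min, ~age_max, ~pregnant, ~lactating, ~value,
      "any", 0L, 3L, FALSE, FALSE, v0_3,
      "any", 4L, 14L, FALSE, FALSE, v4_14,
      "f", 15L, 49L, FALSE, FALSE, f15,
      "m", 15L, 49L, FALSE, FALSE, m15,
      "f", 50L, 150L, FALSE, FALSE, f50,
      "m", 50L, 150L, FALSE, FALSE, m50,
      "f", NA_integer_, NA_integer_, TRUE, FALSE, preg,
      "f", NA_integer_, NA_integer_, FALSE, TRUE, lact
    ) |>
      dplyr::mutate(nutrient = nutrient, value_type = type, basis = basis)
  }
  dplyr::bind_rows(
    band("energy_kcal", "AR", "absolute_per_day", 1000, 1700, 2000, 2550, 1850, 2300, 2200, 2500),
    band("protein_g", "AR", "per_kg_bodyweight", 1.0, 0.9, 0.66, 0.66, 0.66, 0.66, 0.82, 1.0),
    band("vitamin_a_mcg", "AR", "absolute_per_day", 250, 400, 490, 570, 490, 570, 540, 1020),
    band("vitamin_c_mg", "AI", "absolute_per_day", 25, 45, 80, 90, 80, 90, 95, 140),
    band("iron_mg", "AR", "absolute_per_day", 5, 7, 7, 6, 6, 6, 7, 7),
    band("iron_mg", "physiological", "absolute_per_day", 0.6, 0.9, 1.3, 1.0, 0.9, 1.0, 1.6, 1.1),
    band("zinc_mg", "AR", "absolute_per_day", 3.6, 6.2, 6.2, 7.5, 6.2, 7.5, 7.5, 8.9),
    band("zinc_mg", "physiological", "absolute_per_day", 1.1, 1.9, 1.9, 2.4, 1.9, 2.4, 2.4, 2.9),
    band("calcium_mg", "AR", "absolute_per_day", 390, 680, 750, 750, 750, 750, 750, 750)
  )
}

world_body_weights <- function() {
  tibble::tribble(
    ~sex, ~age_min, ~age_max, ~weight_kg,
    "any", 0L, 3L, 12,
    "any", 4L, 14L, 30,
    "f", 15L, 49L, 60,
    "m", 15L, 49L, 70,
    "f", 50L, 150L, 62,
    "m", 50L, 150L, 72
  )
}

## ---------------------------------------------------------------------------
## Independent ground-truth path: direct formula evaluation with base-R loops.
## Deliberately shares no code with the engine (no compute_nutrients, no
## resolve_composition, no weighted_requirement).
## ---------------------------------------------------------------------------

world_ground_truth <- function(world) {
  variants <- c("raw", "processing_only", "flw_cooking_only", "final_best")
  nut <- setdiff(names(world$fct), "fc_code")

  region_of <- stats::setNames(world$countries$region, world$countries$country)
  pop_key <- paste(world$populations$country, world$populations$year)
  pop_of <- stats::setNames(world$populations$population, pop_key)
  refuse_of <- stats::setNames(world$refuse$refuse_fraction, world$refuse$fc_code)
  factor_of <- stats::setNames(world$processing_factors$factor,
                               world$processing_factors$fc_code)
  fct_mat <- as.matrix(world$fct[, nut])
  rownames(fct_mat) <- world$fct$fc_code
  tax <- world$taxonomy
  fsg_of <- stats::setNames(tax$fsg_code, tax$fc_code)
  cereal_of <- stats::setNames(tax$cereal, tax$fc_code)

  flw_key <- paste(world$flw$region, world$flw$fsg_code)
  flw_tbl <- world$flw
  cook_key <- paste(world$cooking$fc_code, world$cooking$nutrient)
  cook_of <- stats::setNames(world$cooking$retention, cook_key)
  split_key <- paste(world$cereal_splits$fc_code, world$cereal_splits$region)

  blend_rule <- world$rules[[1]]
  replace_rule <- world$rules[[2]]

  comp_for <- function(code, country, element) {
    v <- fct_mat[code, ]
    if (code == blend_rule$fc_code && country %in% blend_rule$countries &&
        !element %in% c("imports", "exports")) {
      v <- blend_rule$blend_share * fct_mat[blend_rule$blend_fc, ] +
        (1 - blend_rule$blend_share) * v
    }
    if (code == replace_rule$fc_code && country %in% replace_rule$countries) {
      v <- fct_mat[replace_rule$replacement_fc, ]
    }
    v
  }

  rows <- list()
  for (i in seq_len(nrow(world$flows))) {
    fr <- world$flows[i, ]
    pop <- pop_of[[paste(fr$country, fr$year)]]
    g <- fr$qty_1000mt * 1e9 / (pop * 365)
    region <- region_of[[fr$country]]
    for (variant in variants) {
      proc_on <- variant %in% c("processing_only", "final_best")
      flw_on <- variant %in% c("flw_cooking_only", "final_best")

      pieces <- list(list(form = "primary", comp = fr$fc_code, g = g))
      if (proc_on) {
        sk <- paste(fr$fc_code, region)
        si <- match(sk, split_key)
        if (!is.na(cereal_of[[fr$fc_code]]) && !is.na(si)) {
          sp <- world$cereal_splits[si, ]
          pieces <- list(
            list(form = "refined", comp = paste0(fr$fc_code, "_refined"),
                 g = g * sp$refined_proportion * sp$refined_extraction),
            list(form = "whole", comp = paste0(fr$fc_code, "_whole"),
                 g = g * (1 - sp$refined_proportion) * sp$whole_extraction)
          )
        } else if (fr$fc_code %in% names(factor_of)) {
          pieces[[1]]$g <- g * factor_of[[fr$fc_code]]
        }
      }

      for (p in pieces) {
        ref <- if (fr$fc_code %in% names(refuse_of)) refuse_of[[fr$fc_code]] else 0
        g_ed <- p$g * (1 - ref)
        fretention <- 1
        if (flw_on && fr$element == "food") {
          fi <- match(paste(region, fsg_of[[fr$fc_code]]), flw_key)
          if (!is.na(fi) && !flw_tbl$exempt[fi]) {
            fretention <- (1 - flw_tbl$postharvest[fi]) *
              (1 - flw_tbl$retail[fi]) * (1 - flw_tbl$consumption[fi])
          }
        }
        comp <- comp_for(p$comp, fr$country, fr$element)
        cook <- rep(1, length(nut)); names(cook) <- nut
        if (flw_on && fr$element == "food") {
          for (k in nut) {
            ck <- paste(p$comp, k)
            if (ck %in% names(cook_of)) cook[k] <- cook_of[[ck]]
          }
        }
        vals <- g_ed * fretention * comp / 100 * cook
        rows[[length(rows) + 1L]] <- data.frame(
          country = fr$country, year = fr$year, fc_code = fr$fc_code,
          form = p$form, element = fr$element, variant = variant,
          g_consumed = g_ed * fretention,
          nutrient = nut, value = unname(vals),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  long <- do.call(rbind, rows)

  excl <- tax$fc_code[tax$exclude_from_production]
  tot_prod <- stats::aggregate(
    value ~ country + year + variant + nutrient,
    data = long[long$element == "production" & !long$fc_code %in% excl, ], sum)
  tot_prod$side <- "production"
  tot_int <- stats::aggregate(
    value ~ country + year + variant + nutrient,
    data = long[long$element == "food", ], sum)
  tot_int$side <- "apparent_intake"
  totals <- tibble::as_tibble(rbind(tot_prod, tot_int))

  ## ---- bioavailability on the final_best food element --------------------
  fb_food <- long[long$variant == "final_best" & long$element == "food", ]
  hsi_of <- stats::setNames(tax$is_hsi, tax$fc_code)
  mfp_of <- stats::setNames(tax$is_mfp, tax$fc_code)

  minerals <- list()
  combos <- unique(fb_food[, c("country", "year")])
  for (j in seq_len(nrow(combos))) {
    cc <- combos$country[j]; yy <- combos$year[j]
    sub <- fb_food[fb_food$country == cc & fb_food$year == yy, ]
    tot_of <- function(k) sum(sub$value[sub$nutrient == k])
    iron_sub <- sub[sub$nutrient == "iron_mg", ]
    heme <- 0.40 * sum(iron_sub$value[hsi_of[iron_sub$fc_code]])
    nonheme <- tot_of("iron_mg") - heme
    mass <- unique(sub[, c("fc_code", "form", "g_consumed")])
    mfp <- sum(mass$g_consumed[mfp_of[mass$fc_code]])
    vc <- tot_of("vitamin_c_mg"); phy <- tot_of("phytate_mg")
    ca <- tot_of("calcium_mg"); poly <- tot_of("polyphenol_mg")
    zn <- tot_of("zinc_mg")

    # hand evaluations of the shipped coefficient sets
    conway <- 9.64 + 0.045 * vc + 0.042 * mfp - 0.0037 * phy - 0.0016 * ca
    rickard <- exp(2.162 + 0.094 * log1p(vc) + 0.135 * log1p(mfp) -
                     0.231 * log1p(phy) - 0.067 * log1p(poly) -
                     0.052 * log1p(ca))
    armah <- exp(6.294 - 0.709 * log(21.7) + 0.119 * log(vc + 0.05) +
                   0.006 * mfp - 0.0003 * poly - 0.247 * log(phy + 0.05) -
                   0.137 * log(ca + 0.05) - 0.083 * log(nonheme + 0.05))
    cl <- function(p) min(max(p / 100, 0.001), 1)
    fr_con <- cl(conway); fr_ric <- cl(rickard); fr_arm <- cl(armah)

    tdz <- zn / 65.38; tdp <- phy / 660.04
    a <- 0.091 + tdz + 0.033 * (1 + tdp / 0.680)
    taz <- 0.5 * (a - sqrt(a^2 - 4 * 0.091 * tdz)) * 65.38

    minerals[[length(minerals) + 1L]] <- data.frame(
      country = cc, year = yy, heme_iron = heme, nonheme_iron = nonheme,
      mfp = mfp, zinc = zn, phytate = phy, calcium = ca, vitamin_c = vc,
      polyphenols = poly,
      iron_absorption_fraction_conway = fr_con,
      iron_absorption_fraction_rickard = fr_ric,
      iron_absorption_fraction_armah = fr_arm,
      iron_bioavailable_conway = 0.25 * heme + nonheme * fr_con,
      iron_bioavailable_rickard = 0.25 * heme + nonheme * fr_ric,
      iron_bioavailable_armah = 0.25 * heme + nonheme * fr_arm,
      zinc_absorbed = taz, stringsAsFactors = FALSE
    )
  }
  minerals <- tibble::as_tibble(do.call(rbind, minerals))

  nnrd <- world_gt_nnrd(world)

  ## ---- adequacy (final_best intake; absorbed basis for iron and zinc) ----
  fb_int <- totals[totals$variant == "final_best" &
                     totals$side == "apparent_intake", ]
  adeq <- list()
  for (j in seq_len(nrow(combos))) {
    cc <- combos$country[j]; yy <- combos$year[j]
    mm <- minerals[minerals$country == cc & minerals$year == yy, ]
    for (k in c("energy_kcal", "protein_g", "vitamin_a_mcg", "vitamin_c_mg",
                "iron_mg", "zinc_mg", "calcium_mg")) {
      std <- if (k %in% c("iron_mg", "zinc_mg")) "physiological"
             else if (k == "vitamin_c_mg") "AI" else "AR"
      req <- nnrd$requirement[nnrd$country == cc & nnrd$year == yy &
                                nnrd$nutrient == k & nnrd$standard_used == std]
      value <- if (k == "iron_mg") mm$iron_bioavailable_rickard
               else if (k == "zinc_mg") mm$zinc_absorbed
               else fb_int$value[fb_int$country == cc & fb_int$year == yy &
                                   fb_int$nutrient == k]
      pct <- value / req * 100
      gap <- pct - 100
      adeq[[length(adeq) + 1L]] <- data.frame(
        country = cc, year = yy, nutrient = k, side = "apparent_intake",
        pc_value = value, pc_requirement = req, standard_used = std,
        percent_of_requirement = pct, percent_gap = gap,
        gap_bin = min(max(floor(gap / 15) + 6, 1), 10),
        stringsAsFactors = FALSE
      )
    }
  }
  adequacy <- tibble::as_tibble(do.call(rbind, adeq))

  ## ---- deficit summary for vitamin A -------------------------------------
  deficits <- list()
  for (yy in unique(adequacy$year)) {
    sub <- adequacy[adequacy$year == yy & adequacy$nutrient == "vitamin_a_mcg" &
                      adequacy$pc_value < adequacy$pc_requirement, ]
    popv <- pop_of[paste(sub$country, yy)]
    deficits[[as.character(yy)]] <- list(
      countries = sub$country,
      annual_deficit = sum((sub$pc_requirement - sub$pc_value) * popv) * 365
    )
  }

  list(totals = totals, flow_nutrients = tibble::as_tibble(long),
       minerals = minerals, nnrd = nnrd, adequacy = adequacy,
       deficit_vitamin_a = deficits)
}

world_gt_nnrd <- function(world) {
  drvs <- world$drvs
  bw <- world$body_weights
  out <- list()
  combos <- unique(world$demographics[, c("country", "year")])
  specs <- unique(drvs[, c("nutrient", "value_type")])
  for (j in seq_len(nrow(combos))) {
    cc <- combos$country[j]; yy <- combos$year[j]
    cells <- world$demographics[world$demographics$country == cc &
                                  world$demographics$year == yy, ]
    rp <- world$reproductive[world$reproductive$country == cc &
                               world$reproductive$year == yy, ]
    preg <- rp$live_births * 40 / 52 + rp$induced_abortions * 10 / 52 +
      rp$miscarriages * 10 / 52
    lact <- rp$live_births * 0.5
    elig <- cells$sex == "f" & cells$age >= 15 & cells$age <= 49
    pool <- sum(cells$count[elig])
    shrink <- 1 - (preg + lact) / pool
    total_pop <- sum(cells$count)

    band_of <- function(age) {
      if (age <= 3) "b0" else if (age <= 14) "b4" else if (age <= 49) "b15" else "b50"
    }
    bw_of <- function(age, sex) {
      if (age <= 3) 12 else if (age <= 14) 30
      else if (age <= 49) (if (sex == "f") 60 else 70)
      else (if (sex == "f") 62 else 72)
    }
    for (s in seq_len(nrow(specs))) {
      k <- specs$nutrient[s]; vt <- specs$value_type[s]
      d <- drvs[drvs$nutrient == k & drvs$value_type == vt, ]
      val_of <- function(age, sex, pregnant, lactating) {
        if (pregnant) return(d$value[d$pregnant])
        if (lactating) return(d$value[d$lactating])
        hit <- d[!d$pregnant & !d$lactating &
                   (d$sex == "any" | d$sex == sex) &
                   age >= d$age_min & age <= d$age_max, ]
        hit$value
      }
      acc <- 0
      for (i in seq_len(nrow(cells))) {
        cnt <- cells$count[i] * (if (elig[i]) shrink else 1)
        v <- val_of(cells$age[i], cells$sex[i], FALSE, FALSE)
        if (d$basis[1] == "per_kg_bodyweight") {
          v <- v * bw_of(cells$age[i], cells$sex[i])
        }
        acc <- acc + cnt * v
      }
      vp <- val_of(NA, "f", TRUE, FALSE)
      vl <- val_of(NA, "f", FALSE, TRUE)
      if (d$basis[1] == "per_kg_bodyweight") {
        vp <- vp * 60; vl <- vl * 60
      }
      acc <- acc + preg * vp + lact * vl
      std <- if (vt == "physiological") "physiological" else vt
      out[[length(out) + 1L]] <- data.frame(
        country = cc, year = yy, nutrient = k, requirement = acc / total_pop,
        standard_used = std, stringsAsFactors = FALSE
      )
    }
  }
  tibble::as_tibble(do.call(rbind, out))
}
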