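#' Convert an annual commodity quantity to grams per person per day
#'
#' Food balance sheet elements are reported in 1000 metric tonnes per year.
#' Per-capita daily availability uses a fixed 365-day year:
#' `g/person/day = qty * 1e9 / (population * 365)`.
#'
#' @param qty_1000mt Numeric, quantity in 1000 metric tonnes/year (negative
#'   values permitted, e.g. stock changes).
#' @param population Population (persons); must be > 0.
#' @return Grams per person per day.
#' @export
#' @examples
#' to_per_capita(36.5, 1e6)  # 100 g/person/day
to_per_capita <- function(qty_1000mt, population) {
  if (any(!is.finite(population)) || any(population <= 0)) {
    stop("population must be positive", call. = FALSE)
  }
  qty_1000mt * 1e9 / (population * 365)
}

#' Split a cereal grain supply into refined and whole-grain flour
#'
#' Milling extraction rates convert grain mass to flour mass: the refined
#' stream keeps `refined_proportion` of the grain milled at
#' `refined_extraction` (e.g. 0.72 for straight-grade wheat flour), the rest
#' is milled whole at `whole_extraction` (1.0 for whole-grain flours). Total
#' cereal consumption is taken as the sum of the two flour streams.
#'
#' @param grain_g_day Grain supply, g/person/day (>= 0).
#' @param refined_proportion Share of grain destined for refined flour, in
#'   \[0, 1\].
#' @param refined_extraction,whole_extraction Extraction rates in (0, 1\].
#' @return Named list with `refined` and `whole` flour in g/person/day.
#' @export
#' @examples
#' split_cereal_flours(100, 0.8, 0.72, 1.0)  # refined 57.6, whole 20
split_cereal_flours <- function(grain_g_day, refined_proportion,
                                refined_extraction, whole_extraction) {
  if (any(grain_g_day < 0)) stop("grain quantity must be >= 0", call. = FALSE)
  if (any(refined_proportion < 0 | refined_proportion > 1)) {
    stop("refined_proportion must lie in [0, 1]", call. = FALSE)
  }
  if (any(refined_extraction <= 0 | refined_extraction > 1) ||
      any(whole_extraction <= 0 | whole_extraction > 1)) {
    stop("extraction rates must lie in (0, 1]", call. = FALSE)
  }
  list(
    refined = grain_g_day * refined_proportion * refined_extraction,
    whole = grain_g_day * (1 - refined_proportion) * whole_extraction
  )
}

#' Apply a primary-commodity-to-consumed-form processing factor
#'
#' Factors below 1 represent extraction losses (sugar cane 0.11 to raw
#' sugar); factors above 1 represent dilution into the consumed form (tea
#' leaves 119.05 to brewed tea).
#'
#' @param g_day Primary-commodity supply, g/person/day.
#' @param factor Positive multiplier.
#' @return As-consumed g/person/day.
#' @export
apply_processing_factor <- function(g_day, factor) {
  if (any(factor <= 0)) stop("processing factor must be > 0", call. = FALSE)
  g_day * factor
}

#' Per-capita daily nutrients from a single flow under a loss-accounting variant
#'
#' Core accounting identity: `base = g_day * (1 - refuse) * proc_retention *
#' composition / 100`. The variant controls which adjustments apply:
#' `raw` uses neither processing nor loss adjustments; `processing_only`
#' applies the processing retention only; `flw_cooking_only` applies food
#' loss & waste (FLW) and cooking retention only; `final_best` applies all
#' three. FLW retention is `(1 - postharvest) * (1 - retail) *
#' (1 - consumption)`, with exempt food subgroups using 1.
#'
#' @param g_day Supply in g/person/day (>= 0).
#' @param composition Named numeric vector, nutrient per 100 g edible portion.
#' @param refuse_fraction Refuse proportion in \[0, 1).
#' @param processing_retention Processing retention multiplier (> 0).
#' @param flw Numeric vector of loss fractions
#'   `c(postharvest =, retail =, consumption =)`, each in \[0, 1); use zeros
#'   (default) for exempt subgroups.
#' @param cooking_retention Named numeric vector of per-nutrient cooking
#'   retention fractions in \[0, 1\]; unnamed scalar recycles; nutrients
#'   absent default to 1.
#' @param variant One of `"raw"`, `"processing_only"`, `"flw_cooking_only"`,
#'   `"final_best"`.
#' @return Named numeric vector of per-capita daily nutrient amounts.
#' @export
#' @examples
#' compute_nutrients(200, c(iron_mg = 2), refuse_fraction = 0.333,
#'                   variant = "processing_only")  # 2.668 mg/day
compute_nutrients <- function(g_day, composition, refuse_fraction = 0,
                              processing_retention = 1,
                              flw = c(postharvest = 0, retail = 0, consumption = 0),
                              cooking_retention = 1,
                              variant = c("final_best", "raw", "processing_only",
                                          "flw_cooking_only")) {
  variant <- match.arg(variant)
  if (g_day < 0) stop("supply must be >= 0", call. = FALSE)
  if (refuse_fraction < 0 || refuse_fraction >= 1) {
    stop("refuse fraction must lie in [0, 1)", call. = FALSE)
  }
  if (processing_retention <= 0) stop("processing retention must be > 0", call. = FALSE)
  if (any(flw < 0 | flw >= 1)) stop("FLW fractions must lie in [0, 1)", call. = FALSE)
  if (any(composition < 0)) stop("composition must be >= 0", call. = FALSE)

  proc <- if (variant %in% c("processing_only", "final_best")) processing_retention else 1
  use_flw <- variant %in% c("flw_cooking_only", "final_best")
  flw_retention <- if (use_flw) prod(1 - flw) else 1

  cook <- rep(1, length(composition))
  names(cook) <- names(composition)
  if (use_flw) {
    if (is.null(names(cooking_retention))) {
      cook[] <- cooking_retention
    } else {
      hit <- intersect(names(cooking_retention), names(cook))
      cook[hit] <- cooking_retention[hit]
    }
  }
  if (any(cook < 0 | cook > 1)) stop("cooking retention must lie in [0, 1]", call. = FALSE)

  g_day * (1 - refuse_fraction) * proc * (composition / 100) * flw_retention * cook
}

element_role <- function(element) {
  dplyr::case_match(element,
    "imports" ~ "import",
    "exports" ~ "export",
    .default = "domestic_retained"
  )
}

#' Compute per-capita nutrient flows for a whole food-system bundle
#'
#' Table-level engine: joins a commodity-flow table with populations,
#' taxonomy, composition, refuse, processing, FLW and cooking-retention
#' tables, and evaluates the accounting identity of [compute_nutrients()] for
#' every (country, year, food category, element) cell under one
#' loss-accounting variant. In processing variants, cereal grain rows with a
#' milling specification are split into refined and whole flour rows (forms
#' `"refined"`/`"whole"`, composition looked up as `<fc>_refined` /
#' `<fc>_whole`), and commodity processing factors (coffee, tea, cocoa,
#' sugar) are applied. FLW and cooking retention apply to the `food` element
#' only, the availability-for-consumption side of the accounts.
#'
#' @param world A list of input tables as produced by [generate_world()] or
#'   [read_world()]: `flows`, `populations`, `countries`, `taxonomy`, `fct`,
#'   `refuse`, `processing_factors`, `cooking`, `flw`, `cereal_splits`, and
#'   optionally `rules`.
#' @param variant Loss-accounting variant, see [compute_nutrients()].
#' @return A list with `mass` (one row per flow cell and form: `g_day`,
#'   `g_edible`, `g_consumed`, `flw_retention`) and `nutrients` (long tibble:
#'   country, year, fc_code, form, element, nutrient, value).
#' @export
compute_nutrient_flows <- function(world, variant = c("final_best", "raw",
                                                      "processing_only",
                                                      "flw_cooking_only")) {
  variant <- match.arg(variant)
  proc_on <- variant %in% c("processing_only", "final_best")
  flw_on <- variant %in% c("flw_cooking_only", "final_best")

  base <- world$flows |>
    dplyr::inner_join(world$populations, by = c("country", "year")) |>
    dplyr::left_join(world$countries, by = "country") |>
    dplyr::left_join(world$taxonomy |>
                       dplyr::select("fc_code", "fsg_code", "cereal"),
                     by = "fc_code") |>
    dplyr::mutate(g_day = to_per_capita(.data$qty_1000mt, .data$population))

  if (proc_on) {
    splits <- world$cereal_splits
    base <- base |>
      dplyr::left_join(splits, by = c("fc_code", "region"))
    split_rows <- base |> dplyr::filter(!is.na(.data$refined_proportion))
    plain_rows <- base |> dplyr::filter(is.na(.data$refined_proportion))

    refined <- split_rows |>
      dplyr::mutate(form = "refined",
                    g_day = .data$g_day * .data$refined_proportion *
                      .data$refined_extraction)
    whole <- split_rows |>
      dplyr::mutate(form = "whole",
                    g_day = .data$g_day * (1 - .data$refined_proportion) *
                      .data$whole_extraction)
    plain_rows <- plain_rows |>
      dplyr::left_join(world$processing_factors, by = "fc_code") |>
      dplyr::mutate(form = "primary",
                    g_day = .data$g_day * dplyr::coalesce(.data$factor, 1)) |>
      dplyr::select(-"factor")
    base <- dplyr::bind_rows(plain_rows, refined, whole) |>
      dplyr::select(-"refined_proportion", -"refined_extraction",
                    -"whole_extraction")
  } else {
    base <- base |> dplyr::mutate(form = "primary")
  }
  base <- base |>
    dplyr::mutate(comp_fc = ifelse(.data$form == "primary", .data$fc_code,
                                   paste0(.data$fc_code, "_", .data$form)))

  base <- base |>
    dplyr::left_join(world$refuse, by = "fc_code") |>
    dplyr::mutate(refuse_fraction = dplyr::coalesce(.data$refuse_fraction, 0),
                  g_edible = .data$g_day * (1 - .data$refuse_fraction))

  if (flw_on) {
    base <- base |>
      dplyr::left_join(world$flw, by = c("region", "fsg_code")) |>
      dplyr::mutate(
        flw_retention = ifelse(
          .data$element == "food" & !dplyr::coalesce(.data$exempt, TRUE),
          (1 - dplyr::coalesce(.data$postharvest, 0)) *
            (1 - dplyr::coalesce(.data$retail, 0)) *
            (1 - dplyr::coalesce(.data$consumption, 0)),
          1
        )
      ) |>
      dplyr::select(-dplyr::any_of(c("postharvest", "retail", "consumption", "exempt")))
  } else {
    base <- base |> dplyr::mutate(flw_retention = 1)
  }
  base <- base |> dplyr::mutate(g_consumed = .data$g_edible * .data$flw_retention)

  # composition resolution (country-override rules fire per flow role)
  rules <- world$rules
  nut_cols <- setdiff(names(world$fct),
                      c("fc_code", "n_source_items", "country_override"))
  combos <- base |>
    dplyr::distinct(.data$comp_fc, .data$country, .data$element) |>
    dplyr::mutate(role = element_role(.data$element))
  comp_list <- purrr::pmap(
    list(combos$comp_fc, combos$country, combos$role),
    function(fc, ctry, role) resolve_composition(world$fct, fc, ctry, role, rules)
  )
  comp_tbl <- dplyr::bind_cols(
    combos |> dplyr::select(-"role"),
    tibble::as_tibble(do.call(rbind, comp_list))
  )

  long <- base |>
    dplyr::left_join(comp_tbl, by = c("comp_fc", "country", "element")) |>
    tidyr::pivot_longer(dplyr::all_of(nut_cols),
                        names_to = "nutrient", values_to = "per100g")

  if (flw_on) {
    long <- long |>
      dplyr::left_join(world$cooking,
                       by = c(comp_fc = "fc_code", "nutrient")) |>
      dplyr::mutate(cook_retention = ifelse(.data$element == "food",
                                            dplyr::coalesce(.data$retention, 1), 1)) |>
      dplyr::select(-dplyr::any_of("retention"))
  } else {
    long <- long |> dplyr::mutate(cook_retention = 1)
  }

  nutrients <- long |>
    dplyr::mutate(value = .data$g_edible * .data$flw_retention *
                    .data$cook_retention * .data$per100g / 100) |>
    dplyr::select("country", "year", "fc_code", "form", "element",
                  "nutrient", "value")

  mass <- base |>
    dplyr::select("country", "year", "fc_code", "form", "element",
                  "g_day", "g_edible", "flw_retention", "g_consumed")

  list(mass = mass, nutrients = nutrients, variant = variant)
}

#' Aggregate nutrient flows to country-year totals
#'
#' The production side sums the `production` element, excluding food
#' categories that are processed forms of other flows (vegetable oils,
#' alcohol, butter, cream, fish oils) to avoid double counting; the
#' apparent-intake side sums the `food` element across all categories.
#'
#' @param nutrient_flows The `nutrients` tibble from
#'   [compute_nutrient_flows()] (or the list itself).
#' @param taxonomy Taxonomy tibble with `fc_code` and
#'   `exclude_from_production`.
#' @param side `"production"` or `"apparent_intake"`.
#' @return Tibble: country, year, nutrient, value (zeros, with a warning, for
#'   country-years with no contributing flows).
#' @export
aggregate_country <- function(nutrient_flows, taxonomy,
                              side = c("apparent_intake", "production")) {
  side <- match.arg(side)
  if (is.list(nutrient_flows) && !is.data.frame(nutrient_flows)) {
    nutrient_flows <- nutrient_flows$nutrients
  }
  grid <- nutrient_flows |>
    tidyr::expand(tidyr::nesting(country, year), nutrient)

  kept <- if (side == "production") {
    keep_fc <- taxonomy$fc_code[!taxonomy$exclude_from_production]
    nutrient_flows |>
      dplyr::filter(.data$element == "production", .data$fc_code %in% keep_fc)
  } else {
    nutrient_flows |> dplyr::filter(.data$element == "food")
  }

  out <- kept |>
    dplyr::group_by(.data$country, .data$year, .data$nutrient) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop") |>
    dplyr::right_join(grid, by = c("country", "year", "nutrient"))
  if (anyNA(out$value)) {
    warning("country-years with no contributing flows filled with zero",
            call. = FALSE)
    out$value[is.na(out$value)] <- 0
  }
  dplyr::arrange(out, .data$country, .data$year, .data$nutrient)
}
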