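#' Default nutrient definitions
#'
#' The set of nutrient variables carried by the synthetic fixtures and the
#' worked examples. Real analyses may supply any conforming definition table:
#' one row per nutrient with a unique `code`, a reporting `unit`, an
#' antinutrient flag (compounds such as phytate that inhibit mineral
#' absorption and have no intake requirement), and the requirement standard
#' the nutrient is assessed against (`AR` average requirement, `AI` adequate
#' intake, `physiological` absorbed-basis requirement used for
#' bioavailability-adjusted iron and zinc, or `none`).
#'
#' @return A tibble with columns `code`, `name`, `unit`, `is_antinutrient`,
#'   `requirement_basis`.
#' @export
#' @examples
#' nutrient_definitions()
nutrient_definitions <- function() {
  tibble::tribble(
    ~code,            ~name,                 ~unit,      ~is_antinutrient, ~requirement_basis,
    "energy_kcal",    "Dietary energy",      "kcal",     FALSE,            "AR",
    "protein_g",      "Protein",             "g",        FALSE,            "AR",
    "fat_g",          "Total fat",           "g",        FALSE,            "none",
    "vitamin_a_mcg",  "Vitamin A",           "mcg_RAE",  FALSE,            "AR",
    "vitamin_c_mg",   "Vitamin C",           "mg",       FALSE,            "AI",
    "iron_mg",        "Iron",                "mg",       FALSE,            "physiological",
    "zinc_mg",        "Zinc",                "mg",       FALSE,            "physiological",
    "calcium_mg",     "Calcium",             "mg",       FALSE,            "AR",
    "phytate_mg",     "Phytate",             "mg",       TRUE,             "none",
    "polyphenol_mg",  "Polyphenols (TAE)",   "mg",       TRUE,             "none"
  )
}

#' Collapse food-composition item matches into one record per food category
#'
#' Food composition tables typically hold several item-level matches for each
#' food category (FC). This collapses them to a single per-100 g record per FC
#' by taking the arithmetic mean across matches for each nutrient. Missing
#' item values are first imputed at their lower bound of zero and the affected
#' (fc_code, nutrient) cells are recorded so that downstream uncertainty
#' analyses can exclude them.
#'
#' @param item_matches Tibble with columns `fc_code`, optionally `item_id`,
#'   and one numeric column per nutrient code (per 100 g edible portion).
#'   `NA` marks a missing item value.
#' @return A tibble with one row per `fc_code`: the mean composition,
#'   `n_source_items`, and an attribute `"imputed"` (tibble of `fc_code`,
#'   `nutrient` cells where zero was imputed), retrievable with
#'   [imputed_cells()].
#' @export
#' @examples
#' m <- tibble::tibble(fc_code = c("beef", "beef"), iron_mg = c(2, 4))
#' collapse_fct(m)$iron_mg  # 3
collapse_fct <- function(item_matches) {
  stopifnot(is.data.frame(item_matches), "fc_code" %in% names(item_matches))
  if (nrow(item_matches) == 0L) {
    stop("no composition item matches supplied", call. = FALSE)
  }
  nut_cols <- setdiff(names(item_matches), c("fc_code", "item_id", "country_override"))
  if (!all(vapply(item_matches[nut_cols], is.numeric, logical(1)))) {
    stop("all nutrient columns must be numeric", call. = FALSE)
  }
  if (any(unlist(item_matches[nut_cols]) < 0, na.rm = TRUE)) {
    stop("composition values must be >= 0", call. = FALSE)
  }

  imputed <- item_matches |>
    tidyr::pivot_longer(dplyr::all_of(nut_cols),
                        names_to = "nutrient", values_to = "value") |>
    dplyr::filter(is.na(.data$value)) |>
    dplyr::distinct(.data$fc_code, .data$nutrient)

  out <- item_matches |>
    dplyr::mutate(dplyr::across(dplyr::all_of(nut_cols), ~ tidyr::replace_na(.x, 0))) |>
    dplyr::group_by(.data$fc_code) |>
    dplyr::summarise(
      n_source_items = dplyr::n(),
      dplyr::across(dplyr::all_of(nut_cols), mean),
      .groups = "drop"
    )
  attr(out, "imputed") <- imputed
  out
}

#' Imputed composition cells recorded by [collapse_fct()]
#' @param fct A collapsed composition table from [collapse_fct()].
#' @return Tibble with columns `fc_code`, `nutrient` (possibly zero rows).
#' @export
imputed_cells <- function(fct) {
  imp <- attr(fct, "imputed")
  if (is.null(imp)) tibble::tibble(fc_code = character(), nutrient = character()) else imp
}

#' Default country-override rules for composition resolution
#'
#' Two rules ship by default, read from the package's YAML rules file:
#' a blend rule for palm oil retained for domestic consumption in tropical
#' rain-belt Sub-Saharan African countries (70% consumed unrefined as red palm
#' oil, whose carotenoid content gives it high vitamin A, with exports and
#' imports always refined), and a replacement rule restricting rice in
#' Bangladesh to the parboiled, polished white form predominantly consumed
#' there. The rules are configuration, not code: new overrides are added by
#' editing the YAML.
#'
#' @param path Path to a YAML rules file; defaults to the shipped file.
#' @return A list of rule specs (`type` "blend" or "replace").
#' @export
composition_rules <- function(path = system.file("extdata", "composition_rules.yaml",
                                                 package = "nbsr")) {
  cfg <- yaml::read_yaml(path)
  cfg$rules
}

#' Resolve the composition record for a food category, country and flow role
#'
#' Looks up the per-100 g composition for `fc_code`, applying any
#' country-override rule that fires. A "blend" rule (e.g. red palm oil) mixes
#' an alternate composition record into the base record at a configured share,
#' but only for domestically retained flows; exports and imports use the base
#' (refined) record. A "replace" rule substitutes a different composition row
#' for a specific country irrespective of flow role.
#'
#' @param fct Collapsed composition table (`fc_code` + nutrient columns).
#' @param fc_code Food category code to resolve.
#' @param country ISO3-style country code.
#' @param flow_role One of `"domestic_retained"`, `"export"`, `"import"`.
#' @param rules List of override rules as from [composition_rules()]; `NULL`
#'   (default) applies no overrides.
#' @return Named numeric vector of nutrient amounts per 100 g edible portion.
#' @export
#' @examples
#' fct <- tibble::tibble(fc_code = c("palm_oil", "palm_oil_red"),
#'                       vitamin_a_mcg = c(0, 5000))
#' rule <- list(list(type = "blend", fc_code = "palm_oil",
#'                   blend_fc = "palm_oil_red", blend_share = 0.7,
#'                   countries = "NGA"))
#' resolve_composition(fct, "palm_oil", "NGA", "domestic_retained", rule)
resolve_composition <- function(fct, fc_code, country,
                                flow_role = c("domestic_retained", "export", "import"),
                                rules = NULL) {
  flow_role <- match.arg(flow_role)
  stopifnot(is.character(fc_code), length(fc_code) == 1L)
  if (!fc_code %in% fct$fc_code) {
    stop("unknown food category: ", fc_code, call. = FALSE)
  }
  if (is.na(country) || !nzchar(country)) stop("unknown country", call. = FALSE)

  nut_cols <- setdiff(names(fct), c("fc_code", "n_source_items", "country_override"))
  row_for <- function(code) {
    v <- unlist(fct[match(code, fct$fc_code), nut_cols])
    stats::setNames(as.numeric(v), nut_cols)
  }
  base <- row_for(fc_code)

  for (rule in rules %||% list()) {
    if (!identical(rule$fc_code, fc_code)) next
    if (identical(rule$type, "replace")) {
      if (country %in% rule$countries) {
        if (!rule$replacement_fc %in% fct$fc_code) {
          stop("replacement composition row missing: ", rule$replacement_fc, call. = FALSE)
        }
        return(row_for(rule$replacement_fc))
      }
    } else if (identical(rule$type, "blend")) {
      if (country %in% rule$countries && flow_role == "domestic_retained") {
        if (!rule$blend_fc %in% fct$fc_code) {
          stop("blend composition row missing: ", rule$blend_fc, call. = FALSE)
        }
        s <- rule$blend_share
        stopifnot(s >= 0, s <= 1)
        return(s * row_for(rule$blend_fc) + (1 - s) * base)
      }
    }
  }
  base
}

#' Validate a food-classification taxonomy
#'
#' Report-only structural checks on the FC/FSG/FG hierarchy: duplicate FC
#' codes, missing or unknown food-group assignments, subgroups with more than
#' one catch-all ("other") category, and heme-iron-source flags outside
#' animal-source foods.
#'
#' @param taxonomy Tibble with columns `fc_code`, `fsg_code`, `fg_code`,
#'   `is_fco`, `is_hsi` (others ignored).
#' @return Tibble of findings (`check`, `detail`); zero rows when well formed.
#' @export
validate_taxonomy <- function(taxonomy) {
  findings <- list()
  note <- function(check, detail) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(check = check, detail = detail)
  }

  dup <- taxonomy$fc_code[duplicated(taxonomy$fc_code)]
  for (d in unique(dup)) note("duplicate_fc", d)

  fgs <- c("starchy_staples", "nutrient_dense_vegetal", "animal_source", "other")
  bad_fg <- taxonomy$fc_code[is.na(taxonomy$fg_code) | !taxonomy$fg_code %in% fgs]
  for (b in bad_fg) note("fc_without_valid_fg", b)

  fco_counts <- taxonomy |>
    dplyr::filter(.data$is_fco) |>
    dplyr::count(.data$fsg_code)
  for (f in fco_counts$fsg_code[fco_counts$n > 1L]) note("fsg_multiple_fco", f)

  hsi_bad <- taxonomy$fc_code[taxonomy$is_hsi & taxonomy$fg_code != "animal_source"]
  for (h in hsi_bad) note("hsi_outside_animal_source", h)

  if (length(findings) == 0L) {
    tibble::tibble(check = character(), detail = character())
  } else {
    dplyr::bind_rows(findings)
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x
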