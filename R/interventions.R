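#' Load intervention specifications (capsule doses, fortificants)
#'
#' Capsule doses: 100K IU = 30,000 mcg retinol, 200K IU = 60,000 mcg.
#' Fortificants: retinol at 3 mg/kg wheat flour (fully available), NaFeEDTA
#' at 35 mg/kg with 10% iron bioavailability, zinc oxide at 30 mg/kg with
#' 30% bioavailability.
#'
#' @param path YAML spec path; defaults to the shipped file.
#' @return List with `capsules` and `fortificants`.
#' @export
intervention_specs <- function(path = system.file("extdata", "intervention_specs.yaml",
                                                  package = "nbsr")) {
  yaml::read_yaml(path)
}

#' Identify deficit countries and aggregate their nutrient gap
#'
#' A country is in deficit when per-capita apparent intake is below the
#' per-capita requirement (on the nutrient's designated standard, absorbed
#' basis for iron/zinc). Daily intake and requirement aggregates are summed
#' over the deficit set only — surpluses elsewhere never offset deficits —
#' and the annual deficit is `sum((pc_req - pc_intake) * population) * 365`.
#'
#' @param adequacy Adequacy records ([adequacy_records()]) for one side.
#' @param populations Tibble: `country`, `year`, `population`.
#' @param nutrient Nutrient code.
#' @param year Year to summarize.
#' @return List: `nutrient`, `year`, `deficit_countries` (character),
#'   `n_countries`, `aggregate_intake`, `aggregate_requirement`
#'   (units/day over deficit countries), `annual_deficit` (units/year).
#' @export
identify_and_aggregate_deficit <- function(adequacy, populations, nutrient, year) {
  rows <- adequacy |>
    dplyr::filter(.data$nutrient == !!nutrient, .data$year == !!year) |>
    dplyr::inner_join(populations, by = c("country", "year")) |>
    dplyr::filter(.data$pc_value < .data$pc_requirement)
  list(
    nutrient = nutrient,
    year = year,
    deficit_countries = rows$country,
    n_countries = nrow(rows),
    aggregate_intake = sum(rows$pc_value * rows$population),
    aggregate_requirement = sum(rows$pc_requirement * rows$population),
    annual_deficit = sum((rows$pc_requirement - rows$pc_value) * rows$population) * 365
  )
}

#' Vitamin A capsules needed to meet young-child annual requirements
#'
#' Divides the total annual vitamin A requirement of infants 6-11 months by
#' the 100K IU capsule content and that of children 1-4 years by the 200K IU
#' capsule content.
#'
#' @param req_infants_mcg,req_children_mcg Annual requirements (mcg
#'   RAE/year).
#' @param doses Capsule contents in mcg: `c(d100k = 30000, d200k = 60000)`.
#' @return Total capsules per year.
#' @export
#' @examples
#' capsules_by_requirement(3e5, 1.2e6)  # 10 + 20 = 30
capsules_by_requirement <- function(req_infants_mcg, req_children_mcg,
                                    doses = c(d100k = 30000, d200k = 60000)) {
  stopifnot(req_infants_mcg >= 0, req_children_mcg >= 0, all(doses > 0))
  req_infants_mcg / doses[["d100k"]] + req_children_mcg / doses[["d200k"]]
}

#' Vitamin A capsules needed under the delivery protocol
#'
#' Protocol: infants 6-11 months receive one 100K IU capsule annually;
#' children 1-4 years receive two 200K IU capsules annually (one every six
#' months).
#'
#' @param n_infants_6_11,n_children_1_4 Head counts.
#' @return Total capsules per year.
#' @export
capsules_by_protocol <- function(n_infants_6_11, n_children_1_4) {
  stopifnot(n_infants_6_11 >= 0, n_children_1_4 >= 0)
  n_infants_6_11 * 1 + n_children_1_4 * 2
}

#' Fortified flour required to fill an annual nutrient deficit
#'
#' `flour = annual_deficit / (level * bioavailability)`, converted to 1000
#' metric tonnes, and expressed as a percent of annual flour consumption
#' (reported rounded half-up to an integer, as conventionally printed; may
#' exceed 100 when even full fortification cannot close the gap).
#'
#' @param annual_deficit Deficit per year in the fortificant nutrient's
#'   native unit (`deficit_unit`).
#' @param level_mg_per_kg Fortificant level, mg nutrient per kg flour.
#' @param bioavailability Absorbable fraction of the fortificant in (0, 1\].
#' @param annual_flour_1000mt Annual flour consumption, 1000 MT/year.
#' @param deficit_unit `"mg"` or `"mcg"`.
#' @return List: `flour_required_1000mt`, `percent_of_consumption`
#'   (unrounded), `percent_reported` (integer, half-up; `NA` when
#'   consumption is zero).
#' @export
#' @examples
#' fortification_required(225870e9, 3, 1, 185211, deficit_unit = "mcg")
fortification_required <- function(annual_deficit, level_mg_per_kg,
                                   bioavailability, annual_flour_1000mt,
                                   deficit_unit = c("mg", "mcg")) {
  deficit_unit <- match.arg(deficit_unit)
  stopifnot(annual_deficit >= 0, level_mg_per_kg > 0,
            bioavailability > 0, bioavailability <= 1)
  deficit_mg <- if (deficit_unit == "mcg") annual_deficit / 1000 else annual_deficit
  flour_kg <- deficit_mg / (level_mg_per_kg * bioavailability)
  flour_1000mt <- flour_kg / 1e6   # 1 thousand MT = 1e6 kg
  if (annual_flour_1000mt > 0) {
    pct <- flour_1000mt / annual_flour_1000mt * 100
    pct_rep <- floor(pct + 0.5)
  } else if (flour_1000mt == 0) {
    pct <- pct_rep <- 0
  } else {
    warning("zero flour consumption with a nonzero deficit", call. = FALSE)
    pct <- pct_rep <- NA_real_
  }
  list(flour_required_1000mt = flour_1000mt,
       percent_of_consumption = pct,
       percent_reported = pct_rep)
}
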