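designated_standards <- function(nnrd, nutrients = nutrient_definitions()) {
  phys <- nutrients$code[nutrients$requirement_basis == "physiological"]
  nnrd |>
    dplyr::distinct(.data$nutrient, .data$standard_used) |>
    dplyr::group_by(.data$nutrient) |>
    dplyr::summarise(standard_used = if (dplyr::first(.data$nutrient) %in% phys &&
                                           "physiological" %in% .data$standard_used) {
      "physiological"
    } else {
      setdiff(.data$standard_used, "physiological")[1]
    }, .groups = "drop")
}

#' Run the full nutrient-accounting pipeline over a world bundle
#'
#' Stages: per-capita nutrient flows under the requested loss-accounting
#' variants; country-year production and apparent-intake totals; diet
#' profiles and bioavailability-adjusted minerals (heme/non-heme iron split,
#' three absorption algorithms, absorbed zinc) on the final-best intake;
#' the weighted requirement database; adequacy records in which iron is
#' assessed as bioavailable iron (default algorithm `rickard`) and zinc as
#' absorbed zinc, both against absorbed-basis (physiological) requirements;
#' deficit summaries for selected nutrients; optionally the Monte Carlo
#' catch-all composition analysis. A manifest records the seed, parameter
#' checksum and package version for exact re-runs.
#'
#' @param world Input bundle ([generate_world()] or [read_world()]).
#' @param variants Loss-accounting variants to compute (the adequacy and
#'   bioavailability stages always use `final_best`, which is added if
#'   absent).
#' @param iron_algorithm Non-heme absorption algorithm for adequacy:
#'   `"rickard"` (default), `"conway"` or `"armah"`.
#' @param params Absorption parameters ([load_absorption_params()]).
#' @param deficit_nutrients Nutrient codes to summarize deficits for.
#' @param mc_draws If > 0, run [sample_fco_totals()] with this many draws.
#' @param seed Seed for stochastic stages (the Monte Carlo analysis).
#' @param outdir Optional directory: stage outputs are written as CSV plus a
#'   JSON manifest.
#' @return List: `nutrient_flows` (per variant), `totals` (long, all
#'   variants and both sides), `profiles`, `minerals`, `nnrd`, `adequacy`,
#'   `deficits`, `mc` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(world, variants = "final_best",
                         iron_algorithm = c("rickard", "conway", "armah"),
                         params = load_absorption_params(),
                         deficit_nutrients = "vitamin_a_mcg",
                         mc_draws = 0, seed = 1, outdir = NULL) {
  iron_algorithm <- match.arg(iron_algorithm)
  for (tbl in c("flows", "populations", "countries", "taxonomy", "fct",
                "demographics", "drvs")) {
    if (is.null(world[[tbl]])) {
      stop("pipeline aborted at stage 'inputs': missing table '", tbl, "'",
           call. = FALSE)
    }
  }
  variants <- union(variants, "final_best")

  nutrient_flows <- lapply(stats::setNames(variants, variants), function(v) {
    compute_nutrient_flows(world, v)
  })
  totals <- purrr::imap_dfr(nutrient_flows, function(nf, v) {
    dplyr::bind_rows(
      aggregate_country(nf, world$taxonomy, "production") |>
        dplyr::mutate(side = "production"),
      aggregate_country(nf, world$taxonomy, "apparent_intake") |>
        dplyr::mutate(side = "apparent_intake")
    ) |>
      dplyr::mutate(variant = v)
  })

  fb <- nutrient_flows[["final_best"]]
  profiles <- diet_profiles(fb, world$taxonomy, params)
  minerals <- bioavailable_minerals(profiles, params)

  nnrd <- build_nnrd(world$demographics, world$reproductive, world$drvs,
                     world$body_weights, world$nutrients %||% nutrient_definitions())

  intake_fb <- totals |>
    dplyr::filter(.data$variant == "final_best",
                  .data$side == "apparent_intake") |>
    dplyr::select("country", "year", "nutrient", "value")
  mineral_values <- minerals |>
    dplyr::select("country", "year",
                  iron_mg = dplyr::all_of(paste0("iron_bioavailable_", iron_algorithm)),
                  zinc_mg = "zinc_absorbed") |>
    tidyr::pivot_longer(c("iron_mg", "zinc_mg"),
                        names_to = "nutrient", values_to = "adj_value")
  adequacy_input <- intake_fb |>
    dplyr::left_join(mineral_values, by = c("country", "year", "nutrient")) |>
    dplyr::mutate(value = dplyr::coalesce(.data$adj_value, .data$value)) |>
    dplyr::select(-"adj_value")

  standards <- designated_standards(nnrd, world$nutrients %||% nutrient_definitions())
  adequacy <- adequacy_records(adequacy_input, nnrd, side = "apparent_intake",
                               standards = standards)

  deficits <- lapply(stats::setNames(deficit_nutrients, deficit_nutrients),
                     function(k) {
    lapply(stats::setNames(unique(adequacy$year), unique(adequacy$year)),
           function(yy) {
      identify_and_aggregate_deficit(adequacy, world$populations, k, yy)
    })
  })

  mc <- NULL
  if (mc_draws > 0 && !is.null(world$fco_candidates)) {
    fco_codes <- names(world$fco_candidates)
    fco_grams <- fb$mass |>
      dplyr::filter(.data$element == "food", .data$fc_code %in% fco_codes) |>
      dplyr::group_by(.data$fc_code) |>
      dplyr::summarise(g = sum(.data$g_consumed), .groups = "drop")
    grams <- stats::setNames(rep(0, length(fco_codes)), fco_codes)
    grams[fco_grams$fc_code] <- fco_grams$g
    nut_cols <- colnames(world$fco_candidates[[1]])
    fixed <- fb$nutrients |>
      dplyr::filter(.data$element == "food", !.data$fc_code %in% fco_codes) |>
      dplyr::group_by(.data$nutrient) |>
      dplyr::summarise(value = sum(.data$value), .groups = "drop")
    fixed_totals <- stats::setNames(rep(0, length(nut_cols)), nut_cols)
    fixed_totals[fixed$nutrient] <- fixed$value
    mc <- sample_fco_totals(world$fco_candidates, grams, fixed_totals,
                            n_draws = mc_draws, seed = seed)
  }

  manifest <- list(
    package = "nbsr",
    version = as.character(utils::packageVersion("nbsr")),
    seed = seed,
    variants = variants,
    iron_algorithm = iron_algorithm,
    absorption_params_checksum = attr(params, "checksum"),
    mc_draws = mc_draws
  )

  out <- list(nutrient_flows = nutrient_flows, totals = totals,
              profiles = profiles, minerals = minerals, nnrd = nnrd,
              adequacy = adequacy, deficits = deficits, mc = mc,
              manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(totals, file.path(outdir, "totals.csv"))
    readr::write_csv(minerals, file.path(outdir, "minerals.csv"))
    readr::write_csv(nnrd, file.path(outdir, "nnrd.csv"))
    readr::write_csv(adequacy, file.path(outdir, "adequacy.csv"))
    if (!is.null(mc)) readr::write_csv(mc$summary, file.path(outdir, "mc_summary.csv"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
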