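#' Load mineral-absorption parameters
#'
#' Reads the YAML parameter file holding the heme-iron assumptions, the
#' coefficient sets of the three non-heme iron absorption algorithms, and the
#' constants of the saturable zinc absorption model. The file's md5 checksum
#' is attached as an attribute so run manifests can pin the exact parameter
#' version used.
#'
#' @param path Parameter file path; defaults to the file shipped with the
#'   package.
#' @return Nested list of parameters with attribute `"checksum"`.
#' @export
load_absorption_params <- function(path = system.file("extdata", "absorption_params.yaml",
                                                      package = "nbsr")) {
  params <- yaml::read_yaml(path)
  attr(params, "checksum") <- unname(tools::md5sum(path))
  params
}

#' Split dietary iron into heme and non-heme fractions
#'
#' A fixed share (default 40%) of the iron supplied by heme-source foods
#' (meat, fish, poultry — flagged `is_hsi` in the taxonomy) is counted as
#' heme iron; everything else, including the remaining 60% of iron in
#' heme-source foods, is non-heme.
#'
#' @param iron_by_fc Named numeric vector, iron mg/person/day per food
#'   category.
#' @param hsi_flags Logical vector (same order/names) flagging heme-iron
#'   source categories.
#' @param heme_fraction Heme share of iron in flagged foods.
#' @return List with `heme` and `nonheme` (mg/person/day).
#' @export
#' @examples
#' split_heme(c(beef = 3, lentils = 5), c(beef = TRUE, lentils = FALSE))
split_heme <- function(iron_by_fc, hsi_flags, heme_fraction = 0.40) {
  stopifnot(length(iron_by_fc) == length(hsi_flags))
  if (any(iron_by_fc < 0)) stop("iron values must be >= 0", call. = FALSE)
  heme <- heme_fraction * sum(iron_by_fc[hsi_flags])
  list(heme = heme, nonheme = sum(iron_by_fc) - heme)
}

eval_algorithm_terms <- function(alg, covariates) {
  total <- alg$intercept
  for (term in alg$terms) {
    if (!term$var %in% names(covariates) || is.na(covariates[[term$var]])) {
      stop("missing covariate for iron absorption algorithm: ", term$var,
           call. = FALSE)
    }
    x <- covariates[[term$var]]
    x <- switch(term$transform,
      linear = x,
      log1p = log1p(x),
      log = log(x + (term$offset %||% 0)),
      stop("unknown transform: ", term$transform, call. = FALSE)
    )
    total <- total + term$coef * x
  }
  total
}

#' Predicted non-heme iron absorption fraction for a national diet
#'
#' Evaluates one of three pluggable diet-level algorithms for non-heme iron
#' absorption: a food group-based linear regression (`"conway"`), a test-meal
#' model with log-transformed enhancer/inhibitor terms (`"rickard"`), and a
#' complete-diet log-linear model anchored on a reference serum ferritin of
#' 21.7 mcg/L (`"armah"`). Coefficients are data, not code: they live in the
#' parameter file (see [load_absorption_params()]) and each algorithm is
#' evaluated from its declared terms. The result is clamped to the parameter
#' file's bounds (default (0.001, 1)).
#'
#' @param profile A diet profile: list or one-row data frame with per-capita
#'   daily `nonheme_iron` (mg), `phytate` (mg), `calcium` (mg), `vitamin_c`
#'   (mg), `mfp` (g, meat+fish+poultry), `polyphenols` (mg).
#' @param algorithm `"rickard"` (default, used for downstream adequacy),
#'   `"conway"` or `"armah"`.
#' @param params Parameters from [load_absorption_params()].
#' @return Absorption fraction in (0, 1).
#' @export
nonheme_bioavailability <- function(profile,
                                    algorithm = c("rickard", "conway", "armah"),
                                    params = load_absorption_params()) {
  algorithm <- match.arg(algorithm)
  alg <- params$iron_algorithms[[algorithm]]
  covariates <- as.list(profile)
  covariates$serum_ferritin <- params$serum_ferritin_ref
  raw <- eval_algorithm_terms(alg, covariates)
  percent <- switch(alg$link,
    identity = raw,
    exp = exp(raw),
    stop("unknown link: ", alg$link, call. = FALSE)
  )
  clamp <- params$clamp %||% c(0.001, 1)
  min(max(percent / 100, clamp[1]), clamp[2])
}

#' Total bioavailable iron from heme and non-heme supplies
#'
#' Heme iron is absorbed at a fixed fraction (default 25%); non-heme iron at
#' the algorithm-predicted fraction. Percent bioavailability is the ratio of
#' total bioavailable to total supply (reported `NA` for a zero diet).
#'
#' @param heme,nonheme Supplies in mg/person/day.
#' @param nonheme_fraction Non-heme absorption fraction in \[0, 1\].
#' @param heme_bioavailability Heme absorption fraction.
#' @return Tibble row: `bioavailable_heme`, `bioavailable_nonheme`,
#'   `total_bioavailable` (mg/day), `percent_bioavailability` (%).
#' @export
#' @examples
#' total_bioavailable_iron(1.2, 10, 0.15)  # 0.30 + 1.50 = 1.80 mg/day
total_bioavailable_iron <- function(heme, nonheme, nonheme_fraction,
                                    heme_bioavailability = 0.25) {
  stopifnot(heme >= 0, nonheme >= 0, nonheme_fraction >= 0, nonheme_fraction <= 1)
  bh <- heme * heme_bioavailability
  bn <- nonheme * nonheme_fraction
  total_in <- heme + nonheme
  tibble::tibble(
    bioavailable_heme = bh,
    bioavailable_nonheme = bn,
    total_bioavailable = bh + bn,
    percent_bioavailability = if (total_in > 0) (bh + bn) / total_in * 100 else NA_real_
  )
}

#' Total absorbed zinc under the saturable phytate-inhibited absorption model
#'
#' Converts daily zinc and phytate intakes to mmol, evaluates the trivariate
#' saturable-absorption model
#' `TAZ = 0.5 * (A - sqrt(A^2 - 4 * Amax * TDZ))` with
#' `A = Amax + TDZ + Kr * (1 + TDP / Kp)`, and converts back to mg/day.
#' Absorption saturates at `Amax` as zinc intake grows and declines
#' monotonically with phytate.
#'
#' @param zinc_mg,phytate_mg Daily intakes (>= 0).
#' @param params Parameters from [load_absorption_params()] (uses the `zinc`
#'   block: `amax`, `kr`, `kp` in mmol/day and the two molar masses).
#' @return Total absorbed zinc, mg/day.
#' @export
#' @examples
#' absorbed_zinc(9.8, 990)
absorbed_zinc <- function(zinc_mg, phytate_mg, params = load_absorption_params()) {
  if (any(zinc_mg < 0) || any(phytate_mg < 0)) {
    stop("zinc and phytate intakes must be >= 0", call. = FALSE)
  }
  z <- params$zinc
  tdz <- zinc_mg / z$molar_mass_zinc      # mg / (g/mol) = mmol
  tdp <- phytate_mg / z$molar_mass_phytate
  a <- z$amax + tdz + z$kr * (1 + tdp / z$kp)
  disc <- a^2 - 4 * z$amax * tdz
  if (any(disc < 0)) stop("negative discriminant: invalid absorption parameters",
                          call. = FALSE)
  taz_mmol <- 0.5 * (a - sqrt(disc))
  taz_mmol * z$molar_mass_zinc
}

#' Build a national diet profile from aggregated intake totals
#'
#' Assembles the covariate set the absorption algorithms need from the
#' apparent-intake side of the nutrient accounts: the heme/non-heme iron
#' split over heme-source food categories, antinutrients, enhancers, and
#' edible (post-refuse, post-FLW) meat+fish+poultry grams.
#'
#' @param nutrient_flows Output list of [compute_nutrient_flows()]
#'   (`final_best` variant recommended).
#' @param taxonomy Taxonomy tibble (`fc_code`, `is_hsi`, `is_mfp`).
#' @param params Absorption parameters.
#' @return Tibble, one row per country-year: `heme_iron`, `nonheme_iron`,
#'   `zinc`, `phytate`, `calcium`, `vitamin_c`, `polyphenols`, `mfp`,
#'   `energy`, `protein`.
#' @export
diet_profiles <- function(nutrient_flows, taxonomy,
                          params = load_absorption_params()) {
  food <- nutrient_flows$nutrients |> dplyr::filter(.data$element == "food")

  iron <- food |>
    dplyr::filter(.data$nutrient == "iron_mg") |>
    dplyr::left_join(taxonomy |> dplyr::select("fc_code", "is_hsi"), by = "fc_code") |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::summarise(
      heme_iron = params$heme$heme_fraction * sum(.data$value[.data$is_hsi]),
      nonheme_iron = sum(.data$value) - .data$heme_iron,
      .groups = "drop"
    )

  totals <- food |>
    dplyr::group_by(.data$country, .data$year, .data$nutrient) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "nutrient", values_from = "value")

  mfp <- nutrient_flows$mass |>
    dplyr::filter(.data$element == "food") |>
    dplyr::left_join(taxonomy |> dplyr::select("fc_code", "is_mfp"), by = "fc_code") |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::summarise(mfp = sum(.data$g_consumed[.data$is_mfp]), .groups = "drop")

  iron |>
    dplyr::left_join(totals, by = c("country", "year")) |>
    dplyr::left_join(mfp, by = c("country", "year")) |>
    dplyr::transmute(
      .data$country, .data$year,
      .data$heme_iron, .data$nonheme_iron,
      zinc = .data$zinc_mg,
      phytate = .data$phytate_mg,
      calcium = .data$calcium_mg,
      vitamin_c = .data$vitamin_c_mg,
      polyphenols = .data$polyphenol_mg,
      mfp = .data$mfp,
      energy = .data$energy_kcal,
      protein = .data$protein_g
    )
}

#' Bioavailability-adjusted mineral supplies per country-year
#'
#' Runs the heme/non-heme split, the three non-heme absorption algorithms and
#' the absorbed-zinc model over a table of diet profiles.
#'
#' @param profiles Output of [diet_profiles()].
#' @param params Absorption parameters.
#' @return Tibble per country-year: heme/non-heme iron, absorption fraction
#'   and bioavailable iron under each algorithm, and `zinc_absorbed` (mg/day).
#' @export
bioavailable_minerals <- function(profiles, params = load_absorption_params()) {
  algs <- names(params$iron_algorithms)
  profiles |>
    dplyr::rowwise() |>
    dplyr::mutate(
      frac = list(stats::setNames(
        vapply(algs, function(a) {
          nonheme_bioavailability(
            list(nonheme_iron = .data$nonheme_iron, phytate = .data$phytate,
                 calcium = .data$calcium, vitamin_c = .data$vitamin_c,
                 polyphenols = .data$polyphenols, mfp = .data$mfp),
            a, params)
        }, numeric(1)), algs)),
      zinc_absorbed = absorbed_zinc(.data$zinc, .data$phytate, params)
    ) |>
    dplyr::ungroup() |>
    tidyr::unnest_wider("frac", names_sep = "_") |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(paste0("frac_", algs)),
      ~ .data$heme_iron * params$heme$heme_bioavailability + .data$nonheme_iron * .x,
      .names = "iron_bioavailable_{sub('frac_', '', .col)}"
    )) |>
    dplyr::rename_with(~ sub("^frac_", "iron_absorption_fraction_", .x),
                       dplyr::starts_with("frac_"))
}
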