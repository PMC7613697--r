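#' Estimate the number of currently pregnant women
#'
#' Duration-weighted count: each pregnancy outcome contributes the fraction
#' of a year a pregnancy of that outcome lasts. Defaults follow the standard
#' surveillance approach of combining live births (40 weeks), induced
#' abortions and miscarriages (10 weeks each); all durations are
#' configurable.
#'
#' @param live_births,induced_abortions,miscarriages Annual outcome counts
#'   (>= 0).
#' @param durations Named year-fraction durations
#'   `c(birth =, abortion =, miscarriage =)`.
#' @return Estimated number of currently pregnant women.
#' @export
#' @examples
#' estimate_pregnant(1000, 0, 0, c(birth = 0.75, abortion = 0, miscarriage = 0))
estimate_pregnant <- function(live_births, induced_abortions = 0, miscarriages = 0,
                              durations = c(birth = 40 / 52, abortion = 10 / 52,
                                            miscarriage = 10 / 52)) {
  if (any(c(live_births, induced_abortions, miscarriages) < 0)) {
    stop("reproductive statistics must be >= 0", call. = FALSE)
  }
  live_births * durations[["birth"]] +
    induced_abortions * durations[["abortion"]] +
    miscarriages * durations[["miscarriage"]]
}

#' Estimate the number of lactating women
#'
#' Live births multiplied by the average period over which breastmilk
#' production remains roughly constant (6 months). The number of infants aged
#' 0-5 months is assumed equal to the number of lactating women who are
#' exclusively breastfeeding.
#'
#' @param live_births Annual live births (>= 0).
#' @param months_constant Months of sustained lactation (default 6).
#' @param exclusive_bf_fraction Fraction exclusively breastfeeding (default
#'   1).
#' @return List with `lactating` and `infants_0_5`.
#' @export
estimate_lactating <- function(live_births, months_constant = 6,
                               exclusive_bf_fraction = 1) {
  if (any(live_births < 0)) stop("live births must be >= 0", call. = FALSE)
  lact <- live_births * months_constant / 12
  list(lactating = lact, infants_0_5 = lact * exclusive_bf_fraction)
}

#' Reallocate pregnant and lactating women out of base age-sex cells
#'
#' Pregnant and lactating women are drawn proportionally from the female
#' cells aged `age_range` and added back as dedicated demographic groups
#' (`pregnant` / `lactating` flags), so total persons are conserved while
#' each group can be matched to its own dietary reference values.
#'
#' @param cells Tibble: `age`, `sex` (`"f"`/`"m"`), `count`, plus any id
#'   columns.
#' @param pregnant_n,lactating_n Counts to reallocate.
#' @param age_range Integer ages eligible (default 15:49).
#' @return `cells` with logical `pregnant`, `lactating` columns and two
#'   appended group rows; counts sum unchanged.
#' @export
reallocate_reproductive <- function(cells, pregnant_n, lactating_n,
                                    age_range = 15:49) {
  cells <- cells |>
    dplyr::mutate(pregnant = FALSE, lactating = FALSE)
  eligible <- cells$sex == "f" & cells$age %in% age_range
  pool <- sum(cells$count[eligible])
  need <- pregnant_n + lactating_n
  if (need > pool) {
    stop("pregnant + lactating exceed the eligible female population",
         call. = FALSE)
  }
  if (need > 0 && pool > 0) {
    cells$count[eligible] <- cells$count[eligible] * (1 - need / pool)
  }
  extra <- cells[rep(which(eligible)[1], 2), ]
  extra$age <- NA_integer_
  extra$count <- c(pregnant_n, lactating_n)
  extra$pregnant <- c(TRUE, FALSE)
  extra$lactating <- c(FALSE, TRUE)
  dplyr::bind_rows(cells, extra)
}

match_drv_rows <- function(cells, drv_n, body_weights) {
  # returns, per cell, the matched DRV value (per-kg basis expanded)
  drv_n <- dplyr::mutate(drv_n, .row = dplyr::row_number())
  idx <- vapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    hit <- which(
      (drv_n$sex == "any" | drv_n$sex == cell$sex) &
        (drv_n$pregnant == cell$pregnant) &
        (drv_n$lactating == cell$lactating) &
        (cell$pregnant | cell$lactating |
           (!is.na(cell$age) & cell$age >= drv_n$age_min & cell$age <= drv_n$age_max))
    )
    if (length(hit) == 0L) {
      stop("no DRV group matches cell: age=", cell$age, " sex=", cell$sex,
           if (cell$pregnant) " pregnant" else "",
           if (cell$lactating) " lactating" else "", call. = FALSE)
    }
    if (length(hit) > 1L) {
      stop("ambiguous DRV match (", length(hit), " groups) for cell: age=",
           cell$age, " sex=", cell$sex, call. = FALSE)
    }
    hit
  }, integer(1))
  matched <- drv_n[idx, ]
  value <- matched$value
  perkg <- matched$basis == "per_kg_bodyweight"
  if (any(perkg)) {
    if (is.null(body_weights)) {
      stop("per-kg DRV basis requires a reference body weight table", call. = FALSE)
    }
    for (i in which(perkg)) {
      cell <- cells[i, ]
      # maternal groups carry no single-year age: use the 15-49 female band
      bw_age <- if (is.na(cell$age)) 30 else cell$age
      w <- body_weights$weight_kg[
        (body_weights$sex == "any" | body_weights$sex == cell$sex) &
          bw_age >= body_weights$age_min & bw_age <= body_weights$age_max
      ]
      if (length(w) != 1L) {
        stop("no unique reference body weight for age=", cell$age, " sex=",
             cell$sex, call. = FALSE)
      }
      value[i] <- value[i] * w
    }
  }
  value
}

#' Demographically weighted per-capita daily requirement for one nutrient
#'
#' Crosses demographic cells (after pregnancy/lactation reallocation) with
#' dietary reference values and returns the population-weighted mean
#' requirement. The standard used follows a preference order: by default the
#' average requirement (`AR`), falling back to adequate intake (`AI`);
#' bioavailability-adjusted iron/zinc pipelines request the `physiological`
#' (absorbed-basis) standard instead. Protein-style per-kg values are
#' expanded with reference body weights before weighting.
#'
#' @param cells Demographic cells with `age`, `sex`, `count`, `pregnant`,
#'   `lactating` (see [reallocate_reproductive()]).
#' @param drvs DRV table: `nutrient`, `sex` (`"f"`,`"m"`,`"any"`),
#'   `age_min`, `age_max`, `pregnant`, `lactating`, `value_type` (`AR`, `AI`,
#'   `RI_low`, `RI_high`, `physiological`), `value`, `basis`
#'   (`absolute_per_day` or `per_kg_bodyweight`).
#' @param nutrient Nutrient code to evaluate.
#' @param standard `"auto"` (AR else AI) or an explicit `value_type`.
#' @param body_weights Optional reference body-weight table (`sex`,
#'   `age_min`, `age_max`, `weight_kg`).
#' @return One-row tibble: `nutrient`, `requirement` (per-capita/day),
#'   `standard_used`.
#' @export
weighted_requirement <- function(cells, drvs, nutrient, standard = "auto",
                                 body_weights = NULL) {
  if (!all(c("pregnant", "lactating") %in% names(cells))) {
    cells <- dplyr::mutate(cells, pregnant = FALSE, lactating = FALSE)
  }
  drv_n <- drvs[drvs$nutrient == nutrient, ]
  if (nrow(drv_n) == 0L) stop("no DRVs for nutrient: ", nutrient, call. = FALSE)

  if (identical(standard, "auto")) {
    standard_used <- if (any(drv_n$value_type == "AR")) "AR" else "AI"
  } else {
    standard_used <- standard
  }
  drv_n <- drv_n[drv_n$value_type == standard_used, ]
  if (nrow(drv_n) == 0L) {
    stop("no DRVs with standard ", standard_used, " for nutrient: ", nutrient,
         call. = FALSE)
  }

  value <- match_drv_rows(cells, drv_n, body_weights)
  total <- sum(cells$count)
  req <- if (total > 0) sum(cells$count * value) / total else NA_real_
  tibble::tibble(nutrient = nutrient, requirement = req,
                 standard_used = standard_used)
}

#' Build the National Nutrient Requirement Database (NNRD)
#'
#' For every country-year: estimates pregnant and lactating women from
#' reproductive statistics, reallocates them out of the female 15-49 cells,
#' and computes the weighted per-capita requirement for each nutrient. Iron
#' and zinc additionally get a `physiological` (absorbed-basis) row when the
#' DRV table carries that standard, for comparison against
#' bioavailability-adjusted supplies.
#'
#' @param demographics Tibble: `country`, `year`, `age`, `sex`, `count`.
#' @param reproductive Tibble: `country`, `year`, `live_births`,
#'   `induced_abortions`, `miscarriages`.
#' @param drvs DRV table, see [weighted_requirement()].
#' @param body_weights Reference body weights.
#' @param nutrients Nutrient definition table ([nutrient_definitions()]);
#'   rows with `requirement_basis == "none"` are skipped.
#' @param durations Pregnancy durations, see [estimate_pregnant()].
#' @return Tibble: `country`, `year`, `nutrient`, `requirement`,
#'   `standard_used` (one extra row per absorbed-basis mineral).
#' @export
build_nnrd <- function(demographics, reproductive, drvs, body_weights = NULL,
                       nutrients = nutrient_definitions(),
                       durations = c(birth = 40 / 52, abortion = 10 / 52,
                                     miscarriage = 10 / 52)) {
  wanted <- nutrients[nutrients$requirement_basis != "none", ]
  combos <- dplyr::distinct(demographics, .data$country, .data$year)
  purrr::pmap_dfr(combos, function(country, year) {
    cells <- demographics[demographics$country == country &
                            demographics$year == year, ]
    rep_row <- reproductive[reproductive$country == country &
                              reproductive$year == year, ]
    preg <- lact <- 0
    if (nrow(rep_row) == 1L) {
      preg <- estimate_pregnant(rep_row$live_births, rep_row$induced_abortions,
                                rep_row$miscarriages, durations)
      lact <- estimate_lactating(rep_row$live_births)$lactating
    }
    cells <- reallocate_reproductive(cells, preg, lact)
    per_nutrient <- purrr::pmap_dfr(
      wanted[, c("code", "requirement_basis")],
      function(code, requirement_basis) {
        rows <- weighted_requirement(cells, drvs, code, standard = "auto",
                                     body_weights = body_weights)
        if (requirement_basis == "physiological" &&
            any(drvs$nutrient == code & drvs$value_type == "physiological")) {
          rows <- dplyr::bind_rows(
            rows,
            weighted_requirement(cells, drvs, code, standard = "physiological",
                                 body_weights = body_weights)
          )
        }
        rows
      }
    )
    dplyr::mutate(per_nutrient, country = country, year = year,
                  .before = "nutrient")
  })
}
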