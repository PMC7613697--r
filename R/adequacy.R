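#' Per-capita supply as a percent of the per-capita requirement
#' @param pc_value Per-capita daily supply.
#' @param pc_requirement Per-capita daily requirement (> 0).
#' @return Percent of requirement (`value / requirement * 100`).
#' @export
percent_of_requirement <- function(pc_value, pc_requirement) {
  if (any(pc_requirement <= 0)) stop("requirement must be > 0", call. = FALSE)
  pc_value / pc_requirement * 100
}

#' Nutrient density per 2000 kcal of dietary energy
#' @param pc_value Per-capita daily nutrient amount.
#' @param pc_energy_kcal Per-capita daily dietary energy (kcal).
#' @return Amount per 2000 kcal; `NA` with a warning when energy is zero.
#' @export
nutrient_density <- function(pc_value, pc_energy_kcal) {
  out <- pc_value / pc_energy_kcal * 2000
  zero <- pc_energy_kcal <= 0
  if (any(zero)) {
    warning("zero dietary energy: density undefined", call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' Min-max normalize a series onto a 0-100 scale
#'
#' Affine map `(value - min) / (max - min) * 100` over the pooled series
#' (e.g. both study years pooled, production and intake normalized
#' separately). A constant series maps to all zeros with a warning.
#'
#' @param values Numeric vector.
#' @return Normalized vector in \[0, 100\].
#' @export
minmax_normalize <- function(values) {
  rng <- range(values, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    warning("constant series: normalization degenerate, returning zeros",
            call. = FALSE)
    return(rep(0, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1]) * 100
}

#' Bin a percent gap into one of ten 15-point classes
#'
#' Ten ordered classes symmetric about zero with interior edges at -60, -45,
#' ..., +45, +60 and open tails; intervals are half-open `[lower, upper)`, so
#' a gap of exactly 0 falls in the class whose lower bound is 0.
#'
#' @param percent_gap Finite percent difference(s) from requirement.
#' @return Integer bin index 1-10 (1 = most negative).
#' @export
#' @examples
#' bin_gap(c(-7, 0, 200))  # 5, 6, 10
bin_gap <- function(percent_gap) {
  if (any(!is.finite(percent_gap))) stop("percent gap must be finite", call. = FALSE)
  edges <- c(-Inf, seq(-60, 60, by = 15), Inf)
  findInterval(percent_gap, edges, left.open = FALSE)
}

#' Interior edges of the gap classes used by [bin_gap()]
#' @return Tibble: `bin`, `lower`, `upper` (percentage points).
#' @export
gap_classes <- function() {
  edges <- c(-Inf, seq(-60, 60, by = 15), Inf)
  tibble::tibble(bin = 1:10, lower = edges[1:10], upper = edges[2:11])
}

#' Flag implausible observations by interquartile-range fences
#'
#' Flags values outside `[Q1 - k * IQR, Q3 + k * IQR]`, the standard screen
#' for implausible reporting of total dietary energy per capita. With fewer
#' than four observations no flags are set and a warning is issued.
#'
#' @param values Numeric vector (e.g. country-year energy per capita).
#' @param k Fence multiplier (default 1.5).
#' @return Logical vector, `TRUE` = flagged for exclusion.
#' @export
iqr_exclude <- function(values, k = 1.5) {
  if (sum(is.finite(values)) < 4L) {
    warning("fewer than 4 observations: no exclusions flagged", call. = FALSE)
    return(rep(FALSE, length(values)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  values < q[1] - k * iqr | values > q[2] + k * iqr
}

#' Compare two paired series: correlations and percent differences
#'
#' Pearson (magnitude of linear association) and Spearman (rank agreement)
#' correlations with two-sided p-values, plus the elementwise percent
#' difference `(x - y) / y * 100` used to contrast accounting systems.
#' Zero-variance input yields `NA` correlations with a warning.
#'
#' @param x,y Paired numeric series (n >= 3, pairwise finite).
#' @return List: `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#'   `percent_difference` (vector), `n`.
#' @export
compare_series <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need at least 3 finite pairs", call. = FALSE)
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    warning("zero variance: correlations undefined", call. = FALSE)
    pe <- sp <- list(estimate = NA_real_, p.value = NA_real_)
  } else {
    pe <- stats::cor.test(xs, ys, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(xs, ys, method = "spearman"))
  }
  list(
    pearson_r = unname(pe$estimate),
    pearson_p = pe$p.value,
    spearman_rho = unname(sp$estimate),
    spearman_p = sp$p.value,
    percent_difference = (x - y) / y * 100,
    n = sum(ok)
  )
}

#' Adequacy records: supply versus requirement per country-year-nutrient
#'
#' Joins country-year nutrient totals with the NNRD and computes percent of
#' requirement and percent gap (`percent_of_requirement - 100`).
#'
#' @param totals Tibble: `country`, `year`, `nutrient`, `value` (from
#'   [aggregate_country()] or a bioavailability-adjusted equivalent).
#' @param nnrd NNRD tibble from [build_nnrd()].
#' @param side Label recorded in the output (`"apparent_intake"` or
#'   `"production"`).
#' @param standards Optional tibble (`nutrient`, `standard_used`) selecting
#'   which requirement standard to join per nutrient; default takes the
#'   AR/AI (`auto`) rows.
#' @return Tibble with `pc_value`, `pc_requirement`,
#'   `percent_of_requirement`, `percent_gap`, `gap_bin`.
#' @export
adequacy_records <- function(totals, nnrd, side = "apparent_intake",
                             standards = NULL) {
  req <- if (is.null(standards)) {
    nnrd |> dplyr::filter(.data$standard_used != "physiological")
  } else {
    nnrd |> dplyr::inner_join(standards, by = c("nutrient", "standard_used"))
  }
  totals |>
    dplyr::inner_join(req, by = c("country", "year", "nutrient")) |>
    dplyr::transmute(
      .data$country, .data$year, .data$nutrient,
      side = side,
      pc_value = .data$value,
      pc_requirement = .data$requirement,
      standard_used = .data$standard_used,
      percent_of_requirement = percent_of_requirement(.data$value, .data$requirement),
      percent_gap = .data$percent_of_requirement - 100,
      gap_bin = bin_gap(.data$percent_gap)
    )
}
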