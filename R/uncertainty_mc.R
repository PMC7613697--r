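#' Monte Carlo sensitivity of nutrient totals to catch-all category composition
#'
#' Catch-all ("other", not-elsewhere-classified) food categories pool many
#' possible items of unknown proportions. Each draw assigns every catch-all
#' category a random convex combination of its candidate item compositions —
#' symmetric Dirichlet(1) weights, uniform over the simplex — recomputes the
#' global per-capita totals, and summarizes the spread of each nutrient as a
#' percent deviation from the mean-composition baseline. Nutrients whose
#' half-range exceeds +/- 5% of baseline are flagged.
#'
#' @param fco_candidates Named list (one element per catch-all category) of
#'   numeric matrices: rows = candidate items, columns = nutrients per 100 g.
#'   All matrices must share the same nutrient columns.
#' @param fco_grams Named numeric vector, per-capita g/day supplied by each
#'   catch-all category (names match `fco_candidates`).
#' @param fixed_totals Named numeric vector: per-capita daily totals
#'   contributed by all non-catch-all categories (same nutrient names).
#' @param n_draws Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed; fixed for reproducibility.
#' @return List with `summary` (tibble per nutrient: baseline, min, max,
#'   median, `half_range_pct`, `exceeds_5pct`) and `draws` (matrix of totals,
#'   draws x nutrients).
#' @export
sample_fco_totals <- function(fco_candidates, fco_grams, fixed_totals,
                              n_draws = 1000, seed = 1) {
  if (length(fco_candidates) == 0L) {
    stop("empty catch-all candidate set", call. = FALSE)
  }
  stopifnot(n_draws >= 1, setequal(names(fco_candidates), names(fco_grams)))
  nut <- colnames(fco_candidates[[1]])
  for (m in fco_candidates) {
    if (nrow(m) < 1L) stop("empty catch-all candidate set", call. = FALSE)
    stopifnot(identical(colnames(m), nut))
  }
  stopifnot(all(nut %in% names(fixed_totals)))
  fixed <- fixed_totals[nut]

  baseline <- fixed
  for (fco in names(fco_candidates)) {
    baseline <- baseline + fco_grams[[fco]] * colMeans(fco_candidates[[fco]]) / 100
  }

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    expr
  }
  draws <- withr_seed({
    t(vapply(seq_len(n_draws), function(i) {
      tot <- fixed
      for (fco in names(fco_candidates)) {
        m <- fco_candidates[[fco]]
        w <- stats::rgamma(nrow(m), shape = 1)  # Dirichlet(1,...,1)
        w <- w / sum(w)
        tot <- tot + fco_grams[[fco]] * drop(w %*% m) / 100
      }
      tot
    }, numeric(length(nut))))
  })
  colnames(draws) <- nut

  summary <- tibble::tibble(
    nutrient = nut,
    baseline = unname(baseline),
    min = apply(draws, 2, min),
    max = apply(draws, 2, max),
    median = apply(draws, 2, stats::median),
    half_range_pct = ifelse(baseline > 0,
                            (max - min) / 2 / baseline * 100,
                            ifelse(max > min, Inf, 0)),
    exceeds_5pct = half_range_pct > 5
  )
  list(summary = summary, draws = draws, n_draws = n_draws, seed = seed)
}
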