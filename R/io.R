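check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("malformed ", what, " table: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read a commodity-flow table
#'
#' Columns: `country`, `year`, `fc_code`, `element`, `qty_1000mt` (1000
#' metric tonnes/year). Quantities may be negative only for the
#' `stock_change` element; violations are reported with their row numbers.
#'
#' @param path CSV file path.
#' @return Validated tibble.
#' @export
read_flows <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("country", "year", "fc_code", "element", "qty_1000mt"),
                "flow")
  elements <- c("production", "imports", "exports", "stock_change", "feed",
                "seed", "processing", "other_uses", "losses", "food")
  bad_el <- which(!df$element %in% elements)
  if (length(bad_el) > 0L) {
    stop("unknown element(s) at row(s) ", paste(utils::head(bad_el, 5), collapse = ", "),
         ": ", paste(unique(df$element[bad_el]), collapse = ", "), call. = FALSE)
  }
  bad_neg <- which(df$qty_1000mt < 0 & df$element != "stock_change")
  if (length(bad_neg) > 0L) {
    stop("negative quantity outside stock_change at row(s) ",
         paste(utils::head(bad_neg, 5), collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a collapsed food composition table
#' @param path CSV with `fc_code` plus one numeric column per nutrient.
#' @return Validated tibble (all nutrient values >= 0).
#' @export
read_fct <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, "fc_code", "composition")
  nut <- setdiff(names(df), c("fc_code", "n_source_items", "country_override"))
  for (k in nut) {
    bad <- which(df[[k]] < 0)
    if (length(bad) > 0L) {
      stop("negative composition for ", k, " at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Read a demographic count table
#' @param path CSV with `country`, `year`, `age`, `sex`, `count`.
#' @return Validated tibble (counts >= 0, sex in f/m).
#' @export
read_demographics <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("country", "year", "age", "sex", "count"), "demographic")
  if (any(df$count < 0)) stop("negative demographic counts", call. = FALSE)
  if (!all(df$sex %in% c("f", "m"))) {
    stop("sex must be coded f/m", call. = FALSE)
  }
  df
}

#' Read a dietary reference value table
#' @param path CSV in long group format, see [weighted_requirement()].
#' @return Validated tibble.
#' @export
read_drvs <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("nutrient", "sex", "age_min", "age_max", "pregnant",
                      "lactating", "value_type", "value", "basis"), "DRV")
  if (any(df$value < 0)) stop("negative DRV values", call. = FALSE)
  ok_types <- c("AR", "AI", "RI_low", "RI_high", "physiological")
  if (!all(df$value_type %in% ok_types)) {
    stop("unknown DRV value_type(s): ",
         paste(setdiff(unique(df$value_type), ok_types), collapse = ", "),
         call. = FALSE)
  }
  df
}

world_csv_tables <- c("countries", "taxonomy", "fct", "refuse",
                      "processing_factors", "cereal_splits", "flw", "cooking",
                      "flows", "populations", "demographics", "reproductive",
                      "drvs", "body_weights", "nutrients")

#' Write a world bundle to a directory of CSV (and YAML rules) files
#'
#' Emits the CSV dialects every reader in the package consumes, plus
#' `rules.yaml` (composition override rules) and `fco_candidates.csv` (long:
#' `fco_code`, `item_id`, nutrient columns). Ground truth is not written; it
#' is a construction-time artifact.
#'
#' @param world Bundle from [generate_world()] (or a compatible list).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tbl in world_csv_tables) {
    if (!is.null(world[[tbl]])) {
      readr::write_csv(world[[tbl]], file.path(dir, paste0(tbl, ".csv")))
    }
  }
  if (!is.null(world$rules)) {
    yaml::write_yaml(list(rules = world$rules), file.path(dir, "rules.yaml"))
  }
  if (!is.null(world$fco_candidates)) {
    cand <- purrr::imap_dfr(world$fco_candidates, function(m, fc) {
      tibble::as_tibble(m) |>
        dplyr::mutate(fco_code = fc, item_id = rownames(m), .before = 1)
    })
    readr::write_csv(cand, file.path(dir, "fco_candidates.csv"))
  }
  invisible(dir)
}

#' Read a world bundle written by [write_world()]
#' @param dir Directory containing the bundle.
#' @return List of validated tables (same shapes as [generate_world()]
#'   inputs).
#' @export
read_world <- function(dir) {
  path <- function(f) file.path(dir, f)
  world <- list()
  readers <- list(flows = read_flows, fct = read_fct,
                  demographics = read_demographics, drvs = read_drvs)
  for (tbl in world_csv_tables) {
    f <- path(paste0(tbl, ".csv"))
    if (file.exists(f)) {
      world[[tbl]] <- if (tbl %in% names(readers)) {
        readers[[tbl]](f)
      } else {
        readr::read_csv(f, show_col_types = FALSE)
      }
    }
  }
  if (is.null(world$flows)) {
    stop("no flows.csv in ", dir, ": not a world bundle", call. = FALSE)
  }
  if (file.exists(path("rules.yaml"))) {
    world$rules <- yaml::read_yaml(path("rules.yaml"))$rules
  }
  if (file.exists(path("fco_candidates.csv"))) {
    cand <- readr::read_csv(path("fco_candidates.csv"), show_col_types = FALSE)
    world$fco_candidates <- lapply(
      stats::setNames(unique(cand$fco_code), unique(cand$fco_code)),
      function(fc) {
        sub <- cand[cand$fco_code == fc, ]
        m <- as.matrix(sub[, setdiff(names(sub), c("fco_code", "item_id"))])
        rownames(m) <- sub$item_id
        m
      })
  }
  world
}
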