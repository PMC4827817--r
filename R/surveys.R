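#' Read a long-format territory survey table
#'
#' Reads survey records from CSV (canonical) or XLSX and validates them.
#' The canonical schema is one row per visit with columns
#' `block`, `territory`, `year`, `julian_date`, `observed_state`, where
#' the observed state is coded 1 = no owl detected, 2 = single owl,
#' 3 = pair without evidence of reproduction, 4 = reproducing pair.
#' Deposited spreadsheets with other column names are mapped through
#' `col_map`.
#'
#' @param path Path to a `.csv` or `.xlsx` file.
#' @param format `"auto"` (from the file extension), `"csv"`, or `"xlsx"`.
#' @param col_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(block = "Block", territory = "Site")`.
#'   Unmapped canonical names are assumed to be present verbatim.
#' @param season_window Integer length-2 vector of admissible Julian dates
#'   (day-of-year); the default covers 1 March to 31 August.
#' @return A validated survey tibble (see [validate_surveys()]).
#' @export
read_surveys <- function(path, format = c("auto", "csv", "xlsx"),
                         col_map = NULL, season_window = c(60, 243)) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("survey file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the 'readxl' package", call. = FALSE)
    }
    readxl::read_excel(path)
  }
  canonical <- c("block", "territory", "year", "julian_date", "observed_state")
  map <- setNames(canonical, canonical)
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), canonical)
    if (length(bad)) {
      stop("unknown canonical column(s) in col_map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    map[names(col_map)] <- col_map
  }
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::tibble(
    block          = as.character(raw[[map[["block"]]]]),
    territory      = as.character(raw[[map[["territory"]]]]),
    year           = as.integer(raw[[map[["year"]]]]),
    julian_date    = as.integer(raw[[map[["julian_date"]]]]),
    observed_state = as.integer(raw[[map[["observed_state"]]]])
  )
  validate_surveys(df, season_window = season_window)
}

#' Validate a survey tibble
#'
#' Checks the survey-record invariants: state codes in 1..4, Julian dates
#' inside the season window, each territory belonging to exactly one block,
#' and no duplicated (territory, year, julian_date) visits unless
#' `allow_duplicates = TRUE`.
#'
#' @param df Data frame with the canonical survey columns.
#' @inheritParams read_surveys
#' @param allow_duplicates Keep rows that share (territory, year, julian_date).
#' @return The input as a tibble, invisibly validated; attributes untouched.
#' @export
validate_surveys <- function(df, season_window = c(60, 243),
                             allow_duplicates = FALSE) {
  needed <- c("block", "territory", "year", "julian_date", "observed_state")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  bad_state <- which(!(df$observed_state %in% 1:4))
  if (length(bad_state)) {
    stop("observed_state outside {1,2,3,4} in row(s): ",
         paste(utils::head(bad_state, 10L), collapse = ", "),
         if (length(bad_state) > 10L) " ..." else "", call. = FALSE)
  }
  bad_date <- which(df$julian_date < season_window[1] |
                      df$julian_date > season_window[2])
  if (length(bad_date)) {
    stop("julian_date outside season window [", season_window[1], ", ",
         season_window[2], "] in row(s): ",
         paste(utils::head(bad_date, 10L), collapse = ", "), call. = FALSE)
  }
  multi_block <- df |>
    dplyr::distinct(.data$territory, .data$block) |>
    dplyr::count(.data$territory) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi_block)) {
    stop("territory mapped to multiple blocks: ",
         paste(multi_block$territory, collapse = ", "), call. = FALSE)
  }
  if (!allow_duplicates) {
    dup <- duplicated(df[c("territory", "year", "julian_date")])
    if (any(dup)) {
      stop("duplicated (territory, year, julian_date) visits in row(s): ",
           paste(utils::head(which(dup), 10L), collapse = ", "),
           "; pass allow_duplicates = TRUE to keep them", call. = FALSE)
    }
  }
  df
}

#' Write a survey tibble to the canonical CSV format
#'
#' @param df Survey tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surveys <- function(df, path) {
  readr::write_csv(df[, c("block", "territory", "year", "julian_date",
                          "observed_state")], path, progress = FALSE)
  invisible(path)
}

#' Summarize the survey design
#'
#' Computes the design descriptors used to characterize long-term territory
#' monitoring programmes: territory counts per block, territories surveyed
#' per year, the distribution of visits per territory-year, and the
#' within-year span in days between first and last visit.
#'
#' @param df Survey tibble.
#' @return An object of class `design_summary`: a list with elements
#'   `n_territories`, `block_counts`, `per_year`, `visits`, and `span`,
#'   each a tibble (or scalar), with a `print()` method.
#' @export
summarize_design <- function(df) {
  if (!nrow(df)) stop("cannot summarize an empty survey table", call. = FALSE)
  df <- validate_surveys(df, season_window = c(1, 366), allow_duplicates = TRUE)

  block_counts <- df |>
    dplyr::distinct(.data$block, .data$territory) |>
    dplyr::count(.data$block, name = "n_territories")

  per_year_tbl <- df |>
    dplyr::distinct(.data$year, .data$territory) |>
    dplyr::count(.data$year, name = "n_surveyed")

  visits_tbl <- df |>
    dplyr::count(.data$territory, .data$year, name = "n_visits")

  span_tbl <- df |>
    dplyr::group_by(.data$territory, .data$year) |>
    dplyr::summarise(span_days = max(.data$julian_date) - min(.data$julian_date),
                     .groups = "drop")

  out <- list(
    n_territories = dplyr::n_distinct(df$territory),
    block_counts = block_counts,
    per_year = list(
      table = per_year_tbl,
      mean  = mean(per_year_tbl$n_surveyed),
      sd    = if (nrow(per_year_tbl) > 1) sd(per_year_tbl$n_surveyed) else NA_real_,
      range = range(per_year_tbl$n_surveyed)
    ),
    visits = list(
      table  = visits_tbl,
      median = median(visits_tbl$n_visits),
      mean   = mean(visits_tbl$n_visits),
      sd     = if (nrow(visits_tbl) > 1) sd(visits_tbl$n_visits) else NA_real_
    ),
    span = list(
      table  = span_tbl,
      median = median(span_tbl$span_days),
      range  = range(span_tbl$span_days)
    )
  )
  class(out) <- "design_summary"
  out
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Survey design summary\n")
  cat("  territories:", x$n_territories, "\n")
  cat("  per block:",
      paste(sprintf("%s=%d", x$block_counts$block,
                    x$block_counts$n_territories), collapse = ", "), "\n")
  cat(sprintf("  surveyed per year: mean %.1f (SD %.1f; range %d-%d)\n",
              x$per_year$mean, x$per_year$sd,
              x$per_year$range[1], x$per_year$range[2]))
  cat(sprintf("  visits per territory-year: median %g, mean %.2f (SD %.2f)\n",
              x$visits$median, x$visits$mean, x$visits$sd))
  cat(sprintf("  first-to-last visit span: median %g days (range %d-%d)\n",
              x$span$median, x$span$range[1], x$span$range[2]))
  invisible(x)
}

#' Center and scale visit dates
#'
#' Adds a `jd_std` column holding the standardized Julian date,
#' `(julian_date - center) / scale`, with the center (mean) and scale
#' (sample SD, n - 1 denominator) pooled over all records across blocks and
#' years. The pooled values are stored as attributes `jd_center` and
#' `jd_scale` so detection curves can be mapped back to calendar dates.
#'
#' @param df Survey tibble.
#' @param center,scale Optional fixed values (e.g. from a previous fit); by
#'   default computed from `df`.
#' @return `df` with a `jd_std` column and `jd_center`/`jd_scale` attributes.
#' @export
standardize_dates <- function(df, center = NULL, scale = NULL) {
  if (length(unique(df$julian_date)) < 2 && is.null(scale)) {
    stop("all Julian dates identical; cannot compute a date scale",
         call. = FALSE)
  }
  center <- center %||% mean(df$julian_date)
  scale <- scale %||% sd(df$julian_date)
  if (scale <= 0) stop("date scale must be positive", call. = FALSE)
  df$jd_std <- (df$julian_date - center) / scale
  attr(df, "jd_center") <- center
  attr(df, "jd_scale") <- scale
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
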