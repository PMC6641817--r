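#' @title Rounded scenario reporting
#' @name reporting
#' @description
#' Presentation layer: death counts are rounded to the nearest 100 and
#' percent reductions printed to one decimal, with percents derived from the
#' unrounded totals for stability. Reports are pure functions of their
#' inputs (byte-identical on repeat runs).
NULL

#' Round to the nearest hundred
#'
#' Deterministic half-up rounding used for all published death counts: ties
#' (values ending in exactly 50) round away from zero.
#'
#' @param x Non-negative numeric vector.
#' @return Integer-valued numeric vector of multiples of 100.
#' @export
#' @examples
#' round_nearest_100(c(190612.3, 50, 0))
round_nearest_100 <- function(x) {
  if (any(!is.finite(x) | x < 0)) abort("round_nearest_100() requires non-negative finite input")
  floor(x / 100 + 0.5) * 100
}

#' Build the rounded scenario report
#'
#' Turns the unrounded output of [run_scenario_suite()] into the published
#' presentation: one row per scenario in library order, death counts rounded
#' to the nearest 100, prevented counts rounded likewise, and percent
#' reductions (computed from unrounded totals) formatted to one decimal.
#'
#' @param suite Output of [run_scenario_suite()]. Rows must share one
#'   subcondition group per table; mixing groups within a table is an error.
#' @return A tibble of class `preterm_report` with columns `id`, `table`,
#'   `number`, `description`, `incremental_deaths`, `incremental_prevented`,
#'   `incremental_percent` (character, 1 decimal), and the universal
#'   equivalents. Baseline rows carry `NA` percent.
#' @export
build_report <- function(suite) {
  if (nrow(suite) == 0) {
    return(structure(tibble(), class = c("preterm_report", class(tibble()))))
  }
  groups <- distinct(suite, .data$table, .data$subcondition_group)
  if (nrow(groups) != length(unique(groups$table))) {
    abort("all scenarios of a table must be scored on the same subcondition group")
  }
  out <- suite %>%
    mutate(
      incremental_deaths = round_nearest_100(.data$incremental_deaths),
      incremental_prevented = round_nearest_100(.data$incremental_prevented),
      incremental_percent = if_else(.data$number == 1,
                                    NA_character_,
                                    sprintf("%.1f", .data$incremental_percent)),
      universal_deaths = round_nearest_100(.data$universal_deaths),
      universal_prevented = round_nearest_100(.data$universal_prevented),
      universal_percent = if_else(.data$number == 1,
                                  NA_character_,
                                  sprintf("%.1f", .data$universal_percent))
    ) %>%
    select("id", "table", "number", "description",
           "incremental_deaths", "incremental_prevented", "incremental_percent",
           "universal_deaths", "universal_prevented", "universal_percent")
  structure(out, class = c("preterm_report", class(out)))
}

#' Write a scenario report to disk
#'
#' Emits one CSV and one JSON file per scenario table under `dir`, using the
#' published column layout (deaths, deaths prevented, percent).
#'
#' @param report A `preterm_report` from [build_report()].
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  for (tb in unique(report$table)) {
    rows <- filter(report, .data$table == tb)
    csv <- file.path(dir, sprintf("scenario_table_%s.csv", tb))
    json <- file.path(dir, sprintf("scenario_table_%s.json", tb))
    write.csv(as_tibble(rows), csv, row.names = FALSE, na = "")
    jsonlite::write_json(as_tibble(rows), json, auto_unbox = TRUE, digits = NA)
    written <- c(written, csv, json)
  }
  invisible(written)
}

#' @method autoplot preterm_report
#' @export
autoplot.preterm_report <- function(object, level = c("universal", "incremental"),
                                    ...) {
  level <- match.arg(level)
  col <- paste0(level, "_prevented")
  df <- as_tibble(object) %>%
    filter(.data$number != 1) %>%
    mutate(label = paste0(.data$number, ": ", .data$description))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data[[col]]),
                                   y = .data[[col]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~ .data$table, scales = "free_y", ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = sprintf("Preterm deaths prevented (%s coverage)", level)) +
    ggplot2::theme_minimal()
}
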