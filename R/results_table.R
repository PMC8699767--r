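#' Units vocabulary for results tables
#'
#' Every numeric result row carries one of these units.
#' @export
RESULT_UNITS <- c("px", "px2", "um2", "mm2", "percent", "count",
                  "count_per_mm2", "index", "au")

#' Create a results table
#'
#' The long-format table all pipeline stages append to: one row per
#' (condition, replicate, metric) with a value and a unit drawn from the
#' fixed vocabulary [RESULT_UNITS].
#'
#' @param condition,replicate,metric,value,units Parallel vectors (recycled
#'   by `tibble`); may all be empty for an empty table.
#' @return A tibble of class `results_table`.
#' @export
results_table <- function(condition = character(), replicate = character(),
                          metric = character(), value = numeric(),
                          units = character()) {
  tbl <- tibble::tibble(
    condition = as.character(condition),
    replicate = as.character(replicate),
    metric = as.character(metric),
    value = as.numeric(value),
    units = as.character(units)
  )
  validate_results_table(tbl)
  class(tbl) <- c("results_table", class(tbl))
  tbl
}

validate_results_table <- function(tbl) {
  stopifnot(all(c("condition", "replicate", "metric", "value", "units") %in% names(tbl)))
  if (any(!is.finite(tbl$value))) stop("results table values must be finite")
  bad <- setdiff(unique(tbl$units), RESULT_UNITS)
  if (length(bad)) {
    stop(sprintf("unknown units: %s (allowed: %s)",
                 paste(bad, collapse = ", "), paste(RESULT_UNITS, collapse = ", ")))
  }
  invisible(tbl)
}

#' Append rows to a results table
#' @param tbl A [results_table()].
#' @param condition,replicate,metric,value,units Row contents.
#' @return The extended `results_table`.
#' @export
add_result <- function(tbl, condition, replicate, metric, value, units) {
  out <- dplyr::bind_rows(tbl, tibble::tibble(
    condition = as.character(condition), replicate = as.character(replicate),
    metric = as.character(metric), value = as.numeric(value),
    units = as.character(units)))
  validate_results_table(out)
  class(out) <- unique(c("results_table", class(out)))
  out
}

#' Write a results table to CSV
#'
#' UTF-8, "." decimal separator, header
#' `condition,replicate,metric,value,units`, rows in input order. Values
#' survive a read/write round trip to at least 12 significant digits.
#'
#' @param tbl A [results_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(tbl, path) {
  validate_results_table(tbl)
  out <- tbl
  out$value <- vapply(out$value, function(v) format(v, digits = 15, scientific = FALSE,
                                                   trim = TRUE),
                      character(1))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_table()]
#' @param path CSV path.
#' @return A `results_table`.
#' @export
read_table_results <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    condition = readr::col_character(), replicate = readr::col_character(),
    metric = readr::col_character(), value = readr::col_double(),
    units = readr::col_character()), progress = FALSE)
  validate_results_table(tbl)
  class(tbl) <- c("results_table", class(tbl))
  tbl
}
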