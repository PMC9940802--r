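ledger_columns <- c("date", "unit_id", "monitored_patient_days",
                    "calls_averted", "escalations")

#' Read and write daily call ledgers
#'
#' A ledger is a CSV with header
#' `date,unit_id,monitored_patient_days,calls_averted,escalations`
#' (comma-separated, UTF-8, ISO-8601 dates, decimal-point numbers), one
#' row per nursing unit per calendar day. `calls_averted` counts only
#' calls resolved over the audiovisual link without an in-room visit;
#' escalations (calls that did require entering the room) are tracked
#' separately and never contribute to savings. Lines starting with `#`
#' are metadata comments (the generator records its seed there).
#'
#' Validation names the offending data row and field; duplicate
#' `(date, unit_id)` pairs are rejected. Records are returned sorted by
#' date then unit.
#'
#' @param path CSV file path.
#' @param ledger A ledger tibble.
#' @param comment Optional character vector written as `#` metadata lines
#'   before the header.
#' @return `read_ledger()` a validated ledger tibble; `write_ledger()`
#'   the path, invisibly.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_ledger(fixture_ledger_2020(), p)
#' nrow(read_ledger(p))  # 291
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) {
    abort_invalid(sprintf("ledger file not found: %s", path), field = "path")
  }
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort_invalid("ledger file is empty", field = "path")
  }
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), ledger_columns)) {
    abort_invalid(sprintf(
      "ledger header must be exactly `%s` (got `%s`)",
      paste(ledger_columns, collapse = ","), lines[[1]]), field = "header")
  }
  raw <- readr::read_csv(
    I(paste(lines, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )

  n <- nrow(raw)
  parse_count <- function(x, field) {
    ok <- grepl("^[0-9]+$", x)
    if (!all(ok)) {
      i <- which(!ok)[[1]]
      abort_invalid(sprintf("row %d: %s must be a non-negative integer (got `%s`)",
                            i, field, x[[i]]), field = field)
    }
    as.integer(x)
  }
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    i <- which(is.na(dates))[[1]]
    abort_invalid(sprintf("row %d: date `%s` is not an ISO-8601 calendar date",
                          i, raw$date[[i]]), field = "date")
  }
  if (any(is.na(raw$unit_id) | !nzchar(raw$unit_id))) {
    i <- which(is.na(raw$unit_id) | !nzchar(raw$unit_id))[[1]]
    abort_invalid(sprintf("row %d: unit_id must be non-empty", i), field = "unit_id")
  }
  out <- tibble::tibble(
    date = dates,
    unit_id = raw$unit_id,
    monitored_patient_days = parse_count(raw$monitored_patient_days,
                                         "monitored_patient_days"),
    calls_averted = parse_count(raw$calls_averted, "calls_averted"),
    escalations = parse_count(raw$escalations, "escalations")
  )
  key <- paste(out$date, out$unit_id)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[[1]]
    abort_invalid(sprintf("row %d: duplicate record for (%s, %s)",
                          i, out$date[[i]], out$unit_id[[i]]), field = "date")
  }
  dplyr::arrange(out, .data$date, .data$unit_id)
}

#' @rdname read_ledger
#' @export
write_ledger <- function(ledger, path, comment = NULL) {
  stopifnot(all(ledger_columns %in% names(ledger)))
  if (!is.null(comment)) {
    readr::write_lines(paste0("# ", comment), path)
  }
  readr::write_csv(ledger[ledger_columns], path, append = !is.null(comment),
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Aggregate a ledger over a date window
#'
#' Sums averted calls, monitored patient days and escalations over all
#' records whose date lies in the inclusive window `[window_start,
#' window_end]` (defaults: the ledger's full date range), and derives the
#' two published utilisation ratios. Calendar days are counted inclusive
#' of both endpoints. An empty window returns zero totals with both
#' ratios `NA` and a warning — never a silent zero rate.
#'
#' Ratio columns are kept at full precision; display (print, text
#' reports) rounds them half-up to 1 decimal place, the convention of the
#' published figures (8.9 calls per monitored patient day).
#'
#' @param ledger A ledger tibble (see [read_ledger()]).
#' @param window_start,window_end Window bounds (`Date` or `"YYYY-MM-DD"`).
#' @return A one-row tibble: `window_start`, `window_end`,
#'   `n_calendar_days`, `total_calls_averted`,
#'   `total_monitored_patient_days`, `total_escalations`,
#'   `mean_calls_per_calendar_day`, `calls_per_monitored_patient_day`.
#' @examples
#' fixture_ledger_2020() |> aggregate_ledger("2020-03-16", "2020-04-18")
#' @export
aggregate_ledger <- function(ledger, window_start = NULL, window_end = NULL) {
  stopifnot(all(ledger_columns %in% names(ledger)))
  if (nrow(ledger) == 0 && (is.null(window_start) || is.null(window_end))) {
    abort_invalid("cannot infer a window from an empty ledger; give explicit bounds",
                  field = "window_start")
  }
  window_start <- as.Date(window_start %||% min(ledger$date))
  window_end <- as.Date(window_end %||% max(ledger$date))
  if (is.na(window_start) || is.na(window_end)) {
    abort_invalid("window bounds must be calendar dates", field = "window_start")
  }
  if (window_start > window_end) {
    abort_invalid("`window_start` must be <= `window_end`", field = "window_start")
  }
  in_window <- dplyr::filter(ledger, .data$date >= window_start, .data$date <= window_end)
  n_days <- as.integer(window_end - window_start) + 1L
  calls <- sum(in_window$calls_averted)
  monitored <- sum(in_window$monitored_patient_days)

  if (nrow(in_window) == 0) {
    rlang::warn("no ledger records in window; totals are zero and ratios undefined",
                class = "cvm_empty_window")
  }
  tibble::tibble(
    window_start = window_start,
    window_end = window_end,
    n_calendar_days = n_days,
    total_calls_averted = calls,
    total_monitored_patient_days = monitored,
    total_escalations = sum(in_window$escalations),
    mean_calls_per_calendar_day =
      if (nrow(in_window) == 0) NA_real_ else calls / n_days,
    calls_per_monitored_patient_day =
      if (monitored > 0) calls / monitored else NA_real_
  )
}
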