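# Reading trace logs and applying the two preprocessing filters:
# removal of general-use target-action pairs, then omission of actor-weeks
# with fewer than 25 surviving events.

# Internal: canonicalize tokens to `target>action` (whitespace-tolerant
# around the separator, as logs are sometimes printed `target > action`).
canonical_token <- function(x) {
  gsub("[[:space:]]*>[[:space:]]*", ">", trimws(x))
}

# Internal: parse dates under a dialect; NA where unparseable.
parse_dates <- function(x, dialect) {
  switch(dialect,
    dayfirst = as.Date(x, format = "%d.%m.%Y"),
    iso = as.Date(x, format = "%Y-%m-%d"),
    stop("unknown date dialect: ", dialect, call. = FALSE)
  )
}

#' Read a trace log CSV
#'
#' Expects columns `actor_id,date,target_action`. Malformed rows (unparseable
#' date, missing actor id, token without exactly one `>` separator) are
#' dropped and counted; the read fails only if their fraction exceeds
#' `max_error_fraction`.
#'
#' @param path CSV file path.
#' @param date_dialect `"dayfirst"` (`17.6.2019`, the common platform export
#'   format, default) or `"iso"` (`2019-06-17`).
#' @param delimiter field delimiter, default `","`.
#' @param max_error_fraction error if more than this fraction of rows is
#'   malformed.
#' @return tibble `actor_id, date, target_action` with attribute `report`
#'   (list: `rows_read`, `rows_kept`, `rows_malformed`).
#' @export
read_trace_log <- function(path, date_dialect = c("dayfirst", "iso"),
                           delimiter = ",", max_error_fraction = 0.05) {
  date_dialect <- match.arg(date_dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = delimiter, colClasses = "character",
                  check.names = FALSE)
  needed <- c("actor_id", "date", "target_action")
  if (!all(needed %in% names(raw))) {
    stop("missing required columns: ",
         paste(setdiff(needed, names(raw)), collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  dates <- parse_dates(raw$date, date_dialect)
  tokens <- canonical_token(raw$target_action)
  ok <- !is.na(dates) &
    nzchar(trimws(raw$actor_id)) &
    vapply(strsplit(tokens, ">", fixed = TRUE), length, integer(1)) == 2L &
    !grepl("^>|>$", tokens)
  n_bad <- sum(!ok)
  if (n > 0 && n_bad / n > max_error_fraction) {
    stop(sprintf("%d of %d rows malformed (limit %.0f%%)",
                 n_bad, n, 100 * max_error_fraction), call. = FALSE)
  }
  events <- tibble::tibble(
    actor_id = trimws(raw$actor_id[ok]),
    date = dates[ok],
    target_action = tokens[ok]
  )
  attr(events, "report") <- list(rows_read = n, rows_kept = sum(ok),
                                 rows_malformed = n_bad)
  events
}

#' Assign ISO-8601 year and week to events
#'
#' Adds `year` (ISO week-based year) and `week` (1--53) columns; event order
#' is preserved. ISO numbering is used because January-start academic spring
#' semesters ("weeks 1--22") align with ISO weeks.
#'
#' @param events tibble with a `date` column of class `Date`.
#' @return the events with `year` and `week` columns appended.
#' @export
assign_weeks <- function(events) {
  stopifnot(inherits(events$date, "Date"))
  yw <- iso_year_week(events$date)
  events$year <- yw$year
  events$week <- yw$week
  events
}

#' Remove general-use target-action events
#'
#' Drops events whose token is in `removal_list` — by default the six pairs
#' that reflect general platform use rather than a specific task:
#' `r paste(general_use_tokens(), collapse = ", ")`.
#'
#' @param events event tibble with a `target_action` column.
#' @param removal_list tokens to remove; an empty list is the identity.
#' @return filtered events with attribute `removed_counts` (named integer
#'   vector of removed events per token).
#' @export
remove_general_use <- function(events, removal_list = general_use_tokens()) {
  drop <- events$target_action %in% removal_list
  removed <- events$target_action[drop]
  out <- events[!drop, , drop = FALSE]
  counts <- table(factor(removed, levels = removal_list))
  attr(out, "removed_counts") <-
    setNames(as.integer(counts), removal_list)
  out
}

#' Omit low-activity actor-weeks
#'
#' Drops every (actor, year, week) group with fewer than `min_events`
#' recorded target-action pairs. The threshold is strict: a week with exactly
#' `min_events` events is kept. Applied after general-use removal, so the
#' threshold gates meaningful task activity.
#'
#' @param events tibble with `actor_id`, `year`, `week` columns.
#' @param min_events minimum weekly event count to keep (default 25).
#' @return filtered events with attribute `dropped_weeks`, a tibble
#'   `actor_id, year, week, n_events` of omitted groups.
#' @export
filter_low_activity_weeks <- function(events, min_events = 25) {
  grp <- dplyr::count(events, .data$actor_id, .data$year, .data$week,
                      name = "n_events")
  keep_grp <- grp[grp$n_events >= min_events, c("actor_id", "year", "week")]
  out <- dplyr::semi_join(events, keep_grp,
                          by = c("actor_id", "year", "week"))
  attr(out, "dropped_weeks") <- grp[grp$n_events < min_events, , drop = FALSE]
  out
}

#' Run the full preprocessing chain on a trace log
#'
#' Reads (if `x` is a path), assigns ISO weeks, removes general-use events,
#' then omits actor-weeks with fewer than `min_events` surviving events —
#' in that fixed order.
#'
#' @param x a file path or an event tibble (`actor_id, date, target_action`).
#' @param removal_list tokens to remove; default [general_use_tokens()].
#' @param min_events weekly threshold, default 25.
#' @param date_dialect,delimiter passed to [read_trace_log()] when `x` is a
#'   path.
#' @return list with `events` (clean, with `year`/`week`) and `report`
#'   (rows in, removed per rule, rows out).
#' @export
preprocess_events <- function(x, removal_list = general_use_tokens(),
                              min_events = 25,
                              date_dialect = "dayfirst", delimiter = ",") {
  read_report <- NULL
  if (is.character(x) && length(x) == 1L) {
    x <- read_trace_log(x, date_dialect = date_dialect, delimiter = delimiter)
    read_report <- attr(x, "report")
  }
  n_in <- nrow(x)
  ev <- assign_weeks(x)
  ev <- remove_general_use(ev, removal_list)
  removed_counts <- attr(ev, "removed_counts")
  ev <- filter_low_activity_weeks(ev, min_events)
  dropped <- attr(ev, "dropped_weeks")
  report <- list(
    read = read_report,
    rows_in = n_in,
    general_use_removed = as.list(removed_counts),
    low_activity_weeks_dropped = nrow(dropped),
    low_activity_events_dropped = sum(dropped$n_events),
    rows_out = nrow(ev)
  )
  list(events = ev, report = report)
}

#' Write a preprocessing report as JSON
#'
#' @param report the `report` element of [preprocess_events()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_preprocessing_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
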