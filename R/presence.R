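#' Daily presence/absence and occurrence seconds
#'
#' Collapses a detection stream into one row per individual per day.  An
#' individual is scored present (1) on a day if at least two of its
#' detections that day — pooled across receivers — are separated by strictly
#' less than `window_minutes` (default 15 min); otherwise absent (0).
#' Occurrence seconds sum the lengths of all consecutive inter-detection
#' gaps strictly under the window; a gap of exactly `window_minutes` does
#' not qualify.
#'
#' Days with no detections inside each tag's first-to-last detection span
#' are materialized as `present = 0` rows, so the result is a complete daily
#' series per tag.  Supplying `dates` instead reindexes the output onto an
#' explicit day grid.
#'
#' @param detections A tibble with `tag_id` and POSIXct `timestamp`.
#' @param window_minutes The clustering window in minutes.  Default 15.
#' @param dates Optional day grid: either a `Date` vector applied to every
#'   tag, or a data frame with columns `tag_id`, `date`.  When given, the
#'   output has exactly those rows (days without qualifying detections get
#'   `present = 0`).
#'
#' @return A tibble with columns `tag_id`, `date`, `present` (0/1) and
#'   `occurrence_seconds`.
#' @export
daily_presence <- function(detections, window_minutes = 15, dates = NULL) {
  stopifnot(window_minutes > 0)
  w <- window_minutes * 60
  tz <- attr(detections$timestamp, "tzone") %||% "UTC"
  scored <- detections |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = tz)) |>
    dplyr::group_by(.data$tag_id, .data$date) |>
    dplyr::arrange(.data$timestamp, .by_group = TRUE) |>
    dplyr::summarise(
      present = as.integer(dplyr::n() >= 2 &&
                             any(diff(as.numeric(.data$timestamp)) < w)),
      occurrence_seconds = if (dplyr::n() < 2) 0 else {
        gaps <- diff(as.numeric(.data$timestamp))
        sum(gaps[gaps < w])
      },
      .groups = "drop"
    )
  grid <-
    if (is.null(dates)) {
      scored |>
        dplyr::group_by(.data$tag_id) |>
        dplyr::reframe(date = seq(min(.data$date), max(.data$date), by = "day"))
    } else if (is.data.frame(dates)) {
      tibble::tibble(tag_id = as.character(dates$tag_id),
                     date = as.Date(dates$date))
    } else {
      tidyr::expand_grid(tag_id = unique(scored$tag_id),
                         date = as.Date(dates))
    }
  grid |>
    dplyr::left_join(scored, by = c("tag_id", "date")) |>
    dplyr::mutate(
      present = dplyr::coalesce(.data$present, 0L),
      occurrence_seconds = dplyr::coalesce(.data$occurrence_seconds, 0)
    ) |>
    dplyr::arrange(.data$tag_id, .data$date)
}

#' Degree of occurrence per individual
#'
#' The degree of occurrence (DO) is a residency index: the number of days an
#' individual was detected divided by the inclusive span of days over which
#' detections occurred.  By default the span is anchored on the first and
#' last *detected* day; anchoring the start on the tagging date instead
#' (time at liberty) is available via `anchor`.
#'
#' @param presence A daily presence tibble (see [daily_presence()]).
#' @param anchor `"first_detection"` (default) or `"tag_date"`.
#' @param tag_dates Required when `anchor = "tag_date"`: a data frame with
#'   `tag_id` and `tag_date`.
#' @param on_undetected What to do with tags that have no detected day,
#'   for which DO is undefined: `"error"` (default) or `"drop"`.
#'
#' @return A tibble with one row per tag: `first_day`, `last_day`,
#'   `days_detected`, `duration_days`, `degree_of_occurrence`.
#' @export
degree_of_occurrence <- function(presence,
                                 anchor = c("first_detection", "tag_date"),
                                 tag_dates = NULL,
                                 on_undetected = c("error", "drop")) {
  anchor <- match.arg(anchor)
  on_undetected <- match.arg(on_undetected)
  undet <- presence |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(any_det = any(.data$present == 1), .groups = "drop")
  if (any(!undet$any_det)) {
    bad <- undet$tag_id[!undet$any_det]
    if (on_undetected == "error") {
      rlang::abort(paste0("Degree of occurrence undefined (no detected day) for tag(s): ",
                          paste(bad, collapse = ", ")))
    }
    presence <- presence[!presence$tag_id %in% bad, ]
    if (nrow(presence) == 0) rlang::abort("No tags with a detected day.")
  }
  out <- presence |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(
      first_day = min(.data$date[.data$present == 1]),
      last_day = max(.data$date[.data$present == 1]),
      days_detected = sum(.data$present == 1),
      .groups = "drop"
    )
  if (anchor == "tag_date") {
    if (is.null(tag_dates)) {
      rlang::abort("anchor = \"tag_date\" requires `tag_dates`.")
    }
    out <- out |>
      dplyr::left_join(
        dplyr::mutate(tag_dates[, c("tag_id", "tag_date")],
                      tag_date = as.Date(.data$tag_date)),
        by = "tag_id") |>
      dplyr::mutate(first_day = pmin(.data$first_day, .data$tag_date,
                                     na.rm = TRUE)) |>
      dplyr::select(-"tag_date")
  }
  out |>
    dplyr::mutate(
      duration_days = as.integer(.data$last_day - .data$first_day) + 1L,
      degree_of_occurrence = .data$days_detected / .data$duration_days
    )
}

#' Cohort summary of residency
#'
#' Retains individuals with a monitoring span of at least
#' `min_duration_days` (the model's retention rule, default 30 days) and
#' summarises the degree of occurrence over the retained set.
#'
#' @param summaries Output of [degree_of_occurrence()].
#' @param min_duration_days Minimum inclusive monitoring span in days.
#'
#' @return A list with `retained` (the retained per-individual summaries),
#'   `n_retained`, `do_mean`, `do_sd`, `do_min`, `do_max`.
#' @export
cohort_summary <- function(summaries, min_duration_days = 30) {
  stopifnot(min_duration_days >= 1)
  retained <- dplyr::filter(summaries, .data$duration_days >= min_duration_days)
  if (nrow(retained) == 0) {
    rlang::abort(paste0("No individuals with monitoring span >= ",
                        min_duration_days, " days."))
  }
  list(
    retained = retained,
    n_retained = nrow(retained),
    do_mean = mean(retained$degree_of_occurrence),
    do_sd = stats::sd(retained$degree_of_occurrence),
    do_min = min(retained$degree_of_occurrence),
    do_max = max(retained$degree_of_occurrence)
  )
}

#' Write the per-day model table
#'
#' @param presence A daily presence tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_presence <- function(presence, path) {
  readr::write_csv(presence, path)
  invisible(path)
}
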