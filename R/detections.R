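#' Column mapping and parsing rules for a detection export
#'
#' Detection logs come as CSV exports whose column names vary by software
#' version.  A dialect names the three required columns and fixes the time
#' zone in which timestamps are interpreted.  The default matches a
#' VUE-style receiver export.
#'
#' @param tag Name of the column holding the transmitter (tag) identifier.
#' @param receiver Name of the column holding the receiver identifier.
#' @param timestamp Name of the column holding the detection timestamp.
#' @param tz Time zone used to interpret timestamps.  All day-boundary
#'   computations downstream depend on this, so it is fixed once per import.
#' @param datetime_format Optional `strptime()` format string.  When `NULL`,
#'   ISO-like formats (`"%Y-%m-%d %H:%M:%S"` and variants) are tried.
#'
#' @return A list of class `"occ_dialect"`.
#' @export
#' @examples
#' detection_dialect(tag = "tag", receiver = "station", timestamp = "time")
detection_dialect <- function(tag = "Transmitter",
                              receiver = "Receiver",
                              timestamp = "Date and Time (UTC)",
                              tz = "UTC",
                              datetime_format = NULL) {
  structure(
    list(tag = tag, receiver = receiver, timestamp = timestamp,
         tz = tz, datetime_format = datetime_format),
    class = "occ_dialect"
  )
}

parse_timestamps <- function(x, dialect) {
  fmts <- dialect$datetime_format %||%
    c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS", "%Y/%m/%d %H:%M:%OS",
      "%d/%m/%Y %H:%M:%OS")
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = dialect$tz)
  todo <- rep(TRUE, length(x))
  for (f in fmts) {
    if (!any(todo)) break
    p <- as.POSIXct(x[todo], format = f, tz = dialect$tz)
    out[todo][!is.na(p)] <- p[!is.na(p)]
    todo <- is.na(out)
  }
  out
}

#' Read a detection log
#'
#' Reads a CSV of timestamped tag-on-receiver hits, maps columns through a
#' [detection_dialect()], drops exact duplicate rows (with a logged count),
#' and returns records sorted by tag and time.
#'
#' @param path Path to the CSV file.
#' @param dialect A [detection_dialect()].
#'
#' @return A tibble with columns `tag_id`, `receiver_id`, `timestamp`
#'   (POSIXct in the dialect's time zone), sorted by `(tag_id, timestamp)`.
#' @export
read_detections <- function(path, dialect = detection_dialect()) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c(dialect$tag, dialect$receiver, dialect$timestamp)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste0("Missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  ts <- parse_timestamps(raw[[dialect$timestamp]], dialect)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    rlang::abort(paste0("Unparseable timestamp in row(s): ",
                        paste(utils::head(bad, 10), collapse = ", "),
                        if (length(bad) > 10) " ..." else ""))
  }
  out <- tibble::tibble(
    tag_id = raw[[dialect$tag]],
    receiver_id = raw[[dialect$receiver]],
    timestamp = ts
  )
  if (any(!nzchar(out$tag_id)) || anyNA(out$tag_id)) {
    rlang::abort("Empty tag_id in detection log.")
  }
  n0 <- nrow(out)
  out <- dplyr::distinct(out)
  if (nrow(out) < n0) {
    rlang::inform(paste0("Dropped ", n0 - nrow(out), " duplicate detection row(s)."))
  }
  dplyr::arrange(out, .data$tag_id, .data$timestamp)
}

#' Read an individual metadata table
#'
#' @param path Path to a CSV with columns `tag_id`, `sex`
#'   (`female`/`male`/`unknown`), `length_cm`, `stage`, `tag_date`.
#' @param length_range Plausible total-length range in cm; values outside it
#'   are rejected.
#'
#' @return A tibble, one row per tagged individual.
#' @export
read_individuals <- function(path, length_range = c(50, 400)) {
  stopifnot(file.exists(path))
  ind <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("tag_id", "sex", "length_cm", "stage", "tag_date")
  missing_cols <- setdiff(need, names(ind))
  if (length(missing_cols)) {
    rlang::abort(paste0("Missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  ind$tag_id <- as.character(ind$tag_id)
  ind$sex <- tolower(as.character(ind$sex))
  if (!all(ind$sex %in% c("female", "male", "unknown"))) {
    rlang::abort("sex must be one of female, male, unknown")
  }
  ok <- !is.na(ind$length_cm) &
    ind$length_cm >= length_range[1] & ind$length_cm <= length_range[2]
  if (!all(ok)) {
    rlang::abort(paste0("length_cm outside plausible range for tag(s): ",
                        paste(ind$tag_id[!ok], collapse = ", ")))
  }
  ind$tag_date <- as.Date(ind$tag_date)
  tibble::as_tibble(ind[, need])
}

#' Read a daily environmental table
#'
#' @param path Path to a CSV with columns `date`, `temperature_c`,
#'   `chlorophyll` (mg m^-3; strictly positive, its log is modelled).
#'
#' @return A tibble with one row per date.
#' @export
read_environment <- function(path) {
  stopifnot(file.exists(path))
  env <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("date", "temperature_c", "chlorophyll")
  missing_cols <- setdiff(need, names(env))
  if (length(missing_cols)) {
    rlang::abort(paste0("Missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  env$date <- as.Date(env$date)
  if (anyDuplicated(env$date)) rlang::abort("Duplicate dates in environment table.")
  if (any(env$chlorophyll <= 0, na.rm = TRUE)) {
    rlang::abort("chlorophyll must be strictly positive (its log is taken).")
  }
  tibble::as_tibble(env[, need])
}

#' Screen out probable false-positive detections
#'
#' Receiver logs contain spurious tag decodes from colliding transmissions.
#' The screen applied here is the standard single-detection heuristic: a
#' detection survives if and only if at least `min_cluster` detections of the
#' same tag (on any receiver) fall within some sliding window of
#' `window_minutes` that contains it.  With `min_cluster = 1` the input is
#' returned unchanged.  The filter is idempotent.
#'
#' @param detections A detection tibble (`tag_id`, `timestamp`, ...).
#' @param min_cluster Minimum number of same-tag detections required inside
#'   one window.  Default 2.
#' @param window_minutes Window length in minutes.  Default 30.
#'
#' @return The surviving rows, sorted by `(tag_id, timestamp)`.
#' @export
filter_false_positives <- function(detections, min_cluster = 2,
                                   window_minutes = 30) {
  stopifnot(min_cluster >= 1, window_minutes > 0)
  if (nrow(detections) == 0) return(detections)
  if (min_cluster == 1) return(detections)
  w <- window_minutes * 60
  detections <- dplyr::arrange(detections, .data$tag_id, .data$timestamp)
  keep_tag <- function(tt) {
    n <- length(tt)
    keep <- rep(FALSE, n)
    m <- min_cluster
    if (n >= m) {
      # a length-m run with span <= w marks all its members as genuine
      starts <- which(tt[m:n] - tt[1:(n - m + 1)] <= w)
      for (s in starts) keep[s:(s + m - 1)] <- TRUE
    }
    keep
  }
  keep <- unlist(lapply(
    split(as.numeric(detections$timestamp), detections$tag_id),
    keep_tag
  ), use.names = FALSE)
  dropped <- sum(!keep)
  if (dropped > 0) {
    rlang::inform(paste0("False-positive screen removed ", dropped,
                         " isolated detection(s)."))
  }
  detections[keep, ]
}
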