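#' Seasonal harmonic terms for a date
#'
#' Day-of-year seasonality enters the occurrence model through one harmonic
#' pair, \eqn{x_1 = \cos(2\pi t/365)} and \eqn{x_2 = \sin(2\pi t/365)},
#' where `t` is the 1-based ordinal day within the calendar year.  The
#' denominator is fixed at 365; in leap years Feb 29 takes `t = 60` and
#' later days shift by one, a phase distortion of at most 0.3%.
#'
#' @param dates A `Date` vector, or an integer vector of day-of-year values.
#'
#' @return A tibble with columns `t`, `x1`, `x2`.
#' @export
#' @examples
#' seasonal_terms(as.Date("2017-04-01"))
seasonal_terms <- function(dates) {
  t <- if (inherits(dates, "Date")) {
    as.POSIXlt(dates)$yday + 1
  } else {
    as.numeric(dates)
  }
  tibble::tibble(
    t = t,
    x1 = cos(2 * pi * t / 365),
    x2 = sin(2 * pi * t / 365)
  )
}

#' Baseline values used to centre the covariates
#'
#' The design vector is centred by subtracting a baseline so that the
#' intercept is interpretable as the occurrence log-odds at baseline
#' conditions: both harmonics at 0, log-chlorophyll at 0 (1 mg m^-3), and
#' temperature at 28 degrees C.
#'
#' @return A named numeric 4-vector `(x1, x2, x3, x4)`.
#' @export
occ_baseline <- function() {
  c(x1 = 0, x2 = 0, x3 = 0, x4 = 28)
}

#' Centre a covariate vector or table at baseline values
#'
#' @param x Either a numeric vector of length 4 (one day's `(x1, x2, x3,
#'   x4)`), or a data frame with columns `x1` .. `x4`.
#' @param baseline The baseline 4-vector; default [occ_baseline()].
#'
#' @return For a vector, the centred vector `x - baseline`.  For a data
#'   frame, the same frame with columns `x1_star` .. `x4_star` added.
#' @export
center_covariates <- function(x, baseline = occ_baseline()) {
  stopifnot(length(baseline) == 4)
  if (is.data.frame(x)) {
    for (j in 1:4) {
      x[[paste0("x", j, "_star")]] <- x[[paste0("x", j)]] - baseline[j]
    }
    return(x)
  }
  stopifnot(length(x) == 4)
  unname(x - baseline)
}

#' Build the daily covariate table
#'
#' Joins seasonal harmonics to the environmental series, takes the natural
#' log of chlorophyll, and centres everything at the baseline.  Gaps in the
#' environmental series up to `max_gap_days` are filled by linear
#' interpolation; longer gaps remain missing and are dropped with a logged
#' count.
#'
#' @param environment A tibble with `date`, `temperature_c`, `chlorophyll`.
#' @param baseline Baseline 4-vector; default [occ_baseline()].
#' @param max_gap_days Longest run of missing days to interpolate across.
#'
#' @return A tibble with `date`, `t`, `x1` .. `x4`, `x1_star` .. `x4_star`.
#' @export
build_covariates <- function(environment, baseline = occ_baseline(),
                             max_gap_days = 7) {
  stopifnot(nrow(environment) > 0)
  full <- tibble::tibble(
    date = seq(min(environment$date), max(environment$date), by = "day")
  ) |>
    dplyr::left_join(environment, by = "date")
  n_miss0 <- sum(is.na(full$temperature_c) | is.na(full$chlorophyll))
  full$temperature_c <- zoo::na.approx(full$temperature_c, maxgap = max_gap_days,
                                       na.rm = FALSE)
  full$chlorophyll <- zoo::na.approx(full$chlorophyll, maxgap = max_gap_days,
                                     na.rm = FALSE)
  bad <- is.na(full$temperature_c) | is.na(full$chlorophyll)
  if (any(bad)) {
    rlang::inform(paste0("Dropping ", sum(bad),
                         " day(s) without environmental coverage (gap > ",
                         max_gap_days, " days)."))
    full <- full[!bad, ]
  } else if (n_miss0 > 0) {
    rlang::inform(paste0("Interpolated ", n_miss0, " missing environmental day(s)."))
  }
  out <- dplyr::bind_cols(full, seasonal_terms(full$date))
  out$x3 <- log(out$chlorophyll)
  out$x4 <- out$temperature_c
  center_covariates(out, baseline)
}

#' Intercept design from sex and length
#'
#' The model's individual intercepts are a linear function of a male
#' indicator and of total length centred at `length_center` (default 220 cm,
#' an approximate upper bound of size at maturity for both sexes).  An
#' individual whose sex was not recorded gets `male_indicator = NA` and
#' `sex_known = FALSE`; the model marginalizes over its sex.
#'
#' @param individuals A tibble with `tag_id`, `sex`, `length_cm`.
#' @param length_center Centring length in cm.
#'
#' @return A tibble with `tag_id`, `sex`, `male_indicator`, `sex_known`,
#'   `length_centered`.
#' @export
intercept_design <- function(individuals, length_center = 220) {
  if (anyNA(individuals$length_cm)) {
    rlang::abort(paste0("Missing length for tag(s): ",
                        paste(individuals$tag_id[is.na(individuals$length_cm)],
                              collapse = ", ")))
  }
  tibble::tibble(
    tag_id = individuals$tag_id,
    sex = individuals$sex,
    male_indicator = dplyr::case_when(
      individuals$sex == "male" ~ 1L,
      individuals$sex == "female" ~ 0L,
      TRUE ~ NA_integer_
    ),
    sex_known = individuals$sex %in% c("male", "female"),
    length_centered = individuals$length_cm - length_center
  )
}

#' Assemble the daily model table
#'
#' Joins the daily presence series to the centred covariates and the
#' sex/length intercept design, and retains individuals monitored for at
#' least `min_duration_days` (inclusive span of their daily rows).
#' Presence days without covariate coverage are dropped with a logged count.
#'
#' @param presence Output of [daily_presence()].
#' @param covariates Output of [build_covariates()].
#' @param individuals A tibble with `tag_id`, `sex`, `length_cm`.
#' @param min_duration_days Retention threshold in days.  Default 30.
#' @param length_center Centring length in cm.  Default 220.
#'
#' @return A tibble with one row per retained individual-day: `tag_id`,
#'   `date`, `present`, `x1_star` .. `x4_star`, `male_indicator`,
#'   `sex_known`, `length_centered`.
#' @export
assemble_model_table <- function(presence, covariates, individuals,
                                 min_duration_days = 30, length_center = 220) {
  design <- intercept_design(individuals, length_center = length_center)
  tab <- presence |>
    dplyr::inner_join(
      covariates[, c("date", "x2", paste0("x", 1:4, "_star"))],
      by = "date") |>
    dplyr::inner_join(design, by = "tag_id")
  n_lost <- nrow(presence[presence$tag_id %in% design$tag_id, ]) - nrow(tab)
  if (n_lost > 0) {
    rlang::inform(paste0("Dropped ", n_lost,
                         " presence day(s) without covariate coverage."))
  }
  spans <- tab |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(span = as.integer(max(.data$date) - min(.data$date)) + 1L,
                     .groups = "drop")
  keep <- spans$tag_id[spans$span >= min_duration_days]
  tab <- tab[tab$tag_id %in% keep, ]
  if (nrow(tab) == 0) {
    rlang::abort(paste0("No individuals with monitoring span >= ",
                        min_duration_days, " days."))
  }
  dplyr::arrange(tab, .data$tag_id, .data$date)
}

#' Write the assembled model table
#'
#' @param model_table Output of [assemble_model_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_model_table <- function(model_table, path) {
  readr::write_csv(model_table, path)
  invisible(path)
}

#' Correlation between centred temperature and the seasonal sine term
#'
#' Temperature varies smoothly over the year, so after centring at the
#' baseline it is strongly collinear with the seasonal sine harmonic.  This
#' reports the Pearson correlation over the supplied model rows — the
#' quantity to inspect before interpreting the temperature effect.
#'
#' @param x A model table or covariate table containing `x2` (or `x2_star`)
#'   and `x4_star`.
#'
#' @return A single correlation coefficient.
#' @export
temperature_sine_correlation <- function(x) {
  sine <- x[["x2"]] %||% x[["x2_star"]]
  temp <- x[["x4_star"]]
  if (is.null(sine) || is.null(temp)) {
    rlang::abort("Need columns x2 (or x2_star) and x4_star.")
  }
  if (length(sine) < 3) rlang::abort("Need at least 3 rows.")
  if (stats::sd(sine) == 0 || stats::sd(temp) == 0) {
    rlang::abort("Zero variance in temperature or sine term.")
  }
  stats::cor(temp, sine)
}
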