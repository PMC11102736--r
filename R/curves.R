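new_occ_curve <- function(tbl, conditioning) {
  attr(tbl, "conditioning") <- conditioning
  class(tbl) <- c("occ_curve", class(tbl))
  tbl
}

summarise_p <- function(dates, P, level) {
  a <- (1 - level) / 2
  qs <- apply(P, 1, stats::quantile, probs = c(a, 1 - a))
  tibble::tibble(date = dates,
                 p_mean = rowMeans(P),
                 p_lower = qs[1, ],
                 p_upper = qs[2, ])
}

alpha_draws <- function(fit) {
  list(a0 = fit$draws[["alpha0"]], a1 = fit$draws[["alpha1"]],
       a2 = fit$draws[["alpha2"]])
}

#' Fitted occurrence curve for one tagged individual
#'
#' Evaluates each posterior draw of the individual's intercept and slopes
#' over a covariate series and summarises the daily occurrence probability
#' pointwise by its posterior mean and an equal-tailed credible band.
#'
#' @param fit An `occ_fit`.
#' @param tag_id The individual's tag id (must have been in the fit).
#' @param covariates Output of [build_covariates()] for the prediction days.
#' @param level Credible level.  Default 0.95.
#'
#' @return A tibble of class `"occ_curve"`: `date`, `p_mean`, `p_lower`,
#'   `p_upper`.
#' @export
individual_curve <- function(fit, tag_id, covariates, level = 0.95) {
  k <- match(tag_id, fit$index$tag_id)
  if (is.na(k)) rlang::abort(paste0("Unknown tag_id: ", tag_id))
  X <- as.matrix(covariates[, covariate_cols()])
  B <- as.matrix(fit$draws[, paste0("beta[", k, ",", 1:4, "]")])
  b0 <- fit$draws[[paste0("beta0[", k, "]")]]
  P <- stats::plogis(X %*% t(B) +
                       matrix(b0, nrow = nrow(X), ncol = length(b0),
                              byrow = TRUE))
  new_occ_curve(summarise_p(covariates$date, P, level),
                list(type = "individual", tag_id = tag_id, level = level))
}

# T x D probability matrix for a new individual of given sex weight per draw.
# male_w is a per-draw weight in [0,1]: binary draws give an exact latent-sex
# branch, fractional weights give the pi-mixture of the two branches.
new_individual_p <- function(fit, male_w, length_centered, X, beta_new) {
  a <- alpha_draws(fit)
  slope <- X %*% t(beta_new)
  b0_f <- a$a0 + a$a2 * length_centered
  eta_f <- slope + matrix(b0_f, nrow = nrow(X), ncol = length(b0_f), byrow = TRUE)
  eta_m <- eta_f + matrix(a$a1, nrow = nrow(X), ncol = length(a$a1), byrow = TRUE)
  p_f <- stats::plogis(eta_f)
  p_m <- stats::plogis(eta_m)
  t(t(p_f) * (1 - male_w) + t(p_m) * male_w)
}

draw_population_slopes <- function(fit) {
  D <- nrow(fit$draws)
  mu <- as.matrix(fit$draws[, paste0("mu[", 1:4, "]")])
  sigma <- as.matrix(fit$draws[, paste0("sigma[", 1:4, "]")])
  mu + sigma * matrix(stats::rnorm(D * 4), D, 4)
}

#' Expected occurrence curve for a new individual of given sex and length
#'
#' For every posterior draw, individual slopes are drawn from the
#' population-level distributions \eqn{N(\mu_j, \sigma_j)} and the intercept
#' is built from the sex/length fixed effects; the resulting daily
#' probabilities are summarised pointwise.  The band therefore reflects both
#' parameter uncertainty and between-individual variability.
#'
#' @param fit An `occ_fit`.
#' @param sex `"female"` or `"male"`.
#' @param length_cm Total length in cm.
#' @param covariates Output of [build_covariates()] for the prediction days.
#' @param level Credible level.  Default 0.95.
#' @param length_center Centring length used in the fit.  Default 220.
#' @param seed Seed for the population-slope draws.
#'
#' @return A tibble of class `"occ_curve"`.
#' @export
expected_curve <- function(fit, sex = c("female", "male"), length_cm,
                           covariates, level = 0.95, length_center = 220,
                           seed = 1) {
  sex <- match.arg(sex)
  X <- as.matrix(covariates[, covariate_cols()])
  P <- withr::with_seed(seed, {
    beta_new <- draw_population_slopes(fit)
    new_individual_p(fit, male_w = as.numeric(sex == "male"),
                     length_centered = length_cm - length_center,
                     X = X, beta_new = beta_new)
  })
  new_occ_curve(summarise_p(covariates$date, P, level),
                list(type = "expected", sex = sex, length_cm = length_cm,
                     level = level))
}

#' Population-marginal occurrence curve
#'
#' Averages expected occurrence curves, per posterior draw, over a cohort's
#' observed sex/length combinations; by default the fitted cohort is used,
#' with an unrecorded-sex individual entering through its sampled latent
#' sex.  This is the "average shark, average conditions" curve.
#'
#' @param fit An `occ_fit`.
#' @param covariates Output of [build_covariates()] for the prediction days.
#' @param individuals Optional tibble with `sex` and `length_cm` describing
#'   the cohort to average over; default is the fitted cohort.
#' @param level Credible level.  Default 0.95.
#' @param length_center Centring length used in the fit.  Default 220.
#' @param seed Seed for the population-slope draws.
#'
#' @return A tibble of class `"occ_curve"`.
#' @export
marginal_population_curve <- function(fit, covariates, individuals = NULL,
                                      level = 0.95, length_center = 220,
                                      seed = 1) {
  X <- as.matrix(covariates[, covariate_cols()])
  D <- nrow(fit$draws)
  if (is.null(individuals)) {
    members <- lapply(seq_len(nrow(fit$index)), function(k) {
      w <- if (fit$index$sex_known[k]) {
        rep(fit$index$male_indicator[k], D)
      } else {
        fit$draws[[paste0("z[", k, "]")]]
      }
      list(male_w = w, lenc = fit$index$length_centered[k])
    })
  } else {
    if (nrow(individuals) == 0) rlang::abort("Empty cohort.")
    members <- lapply(seq_len(nrow(individuals)), function(k) {
      w <- switch(individuals$sex[k],
                  male = rep(1, D), female = rep(0, D),
                  fit$draws[["pi"]])
      list(male_w = w, lenc = individuals$length_cm[k] - length_center)
    })
  }
  P <- withr::with_seed(seed, {
    acc <- matrix(0, nrow = nrow(X), ncol = D)
    for (mem in members) {
      beta_new <- draw_population_slopes(fit)
      acc <- acc + new_individual_p(fit, mem$male_w, mem$lenc, X, beta_new)
    }
    acc / length(members)
  })
  new_occ_curve(summarise_p(covariates$date, P, level),
                list(type = "marginal", n_members = length(members),
                     level = level))
}

#' Female-minus-male occurrence contrast
#'
#' Pointwise difference in occurrence probability between a female and a
#' male of the same length, in percentage points, propagating the full
#' posterior (shared population-slope draws for the two sexes, so the
#' contrast isolates the sex effect).
#'
#' @inheritParams expected_curve
#'
#' @return A tibble of class `"occ_curve"` whose `p_*` columns hold the
#'   female-minus-male difference in percentage points.
#' @export
sex_difference_curve <- function(fit, length_cm, covariates, level = 0.95,
                                 length_center = 220, seed = 1) {
  X <- as.matrix(covariates[, covariate_cols()])
  Dmat <- withr::with_seed(seed, {
    beta_new <- draw_population_slopes(fit)
    lenc <- length_cm - length_center
    p_f <- new_individual_p(fit, 0, lenc, X, beta_new)
    p_m <- new_individual_p(fit, 1, lenc, X, beta_new)
    100 * (p_f - p_m)
  })
  new_occ_curve(summarise_p(covariates$date, Dmat, level),
                list(type = "sex_contrast", length_cm = length_cm,
                     units = "percentage points", level = level))
}

#' Calendar-month summary of an occurrence curve
#'
#' Bins a fitted curve by calendar month and reports the monthly mean
#' occurrence probability alongside monthly mean temperature and
#' chlorophyll — the numbers behind a polar seasonal display.
#'
#' @param curve An `"occ_curve"`.
#' @param environment A tibble with `date`, `temperature_c`, `chlorophyll`.
#'
#' @return A tibble of class `"occ_polar"`: `month`, `p_mean`,
#'   `temperature_c`, `chlorophyll`.
#' @export
polar_summary <- function(curve, environment) {
  joined <- dplyr::inner_join(tibble::as_tibble(curve), environment,
                              by = "date")
  if (nrow(joined) == 0) rlang::abort("Curve and environment dates do not overlap.")
  out <- joined |>
    dplyr::mutate(month = factor(format(.data$date, "%b"),
                                 levels = month.abb)) |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(p_mean = mean(.data$p_mean),
                     temperature_c = mean(.data$temperature_c),
                     chlorophyll = mean(.data$chlorophyll),
                     .groups = "drop")
  class(out) <- c("occ_polar", class(out))
  out
}

#' Plot an occurrence curve with its credible band
#'
#' @param object An `"occ_curve"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot occ_curve
#' @export
autoplot.occ_curve <- function(object, ...) {
  cond <- attr(object, "conditioning")
  ylab <- if (identical(cond$type, "sex_contrast")) {
    "Female - male occurrence (percentage points)"
  } else {
    "Occurrence probability"
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$date, y = .data$p_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p_lower,
                                      ymax = .data$p_upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

#' Polar seasonal plot of monthly occurrence
#'
#' @param object An `"occ_polar"` summary.
#' @param fill `"temperature_c"` or `"chlorophyll"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot occ_polar
#' @export
autoplot.occ_polar <- function(object, fill = c("temperature_c", "chlorophyll"),
                               ...) {
  fill <- match.arg(fill)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$month, y = .data$p_mean,
                                       fill = .data[[fill]])) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "Mean occurrence probability") +
    ggplot2::theme_minimal()
}
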