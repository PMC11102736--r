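#' Configuration for the synthetic telemetry cohort
#'
#' The generator draws a cohort from the occurrence model's own generative
#' direction: individual slopes from \eqn{N(\mu_j, \sigma_j)}, intercepts
#' from the sex/length fixed effects, seasonal environmental forcing, daily
#' presence as Bernoulli draws, and (via [explode_to_detections()]) raw
#' detection streams consistent with the 15-minute presence rule.
#'
#' Defaults are the "paper-like" preset: a 32-individual cohort spanning
#' 2015–2019 with lengths 160–280 cm, one unrecorded sex, a strong positive
#' sine slope (spring presence, fall absence), a late-August temperature
#' peak around a 25.5 °C mean, and a mean degree of occurrence near 0.37.
#'
#' @param n_individuals Cohort size.
#' @param study_start,study_end Study span (Dates).
#' @param true_alpha Generating `(alpha0, alpha1, alpha2)`.
#' @param true_mu Generating population slope means (cos, sin,
#'   log-chlorophyll, temperature).
#' @param true_sigma Generating between-individual slope SDs (all > 0).
#' @param prop_male Probability that an individual is male.
#' @param length_mean,length_sd,length_min,length_max Total length
#'   distribution in cm (truncated normal).
#' @param unknown_sex_count Number of individuals whose sex is reported as
#'   unrecorded.
#' @param temp_mean,temp_amplitude,temp_phase_day,temp_noise_sd Temperature
#'   model: `temp_mean + temp_amplitude * cos(2*pi*(t - temp_phase_day)/365)`
#'   plus Gaussian noise, in °C.
#' @param chl_log_mean,chl_amplitude,chl_phase_day,chl_noise_sd Chlorophyll
#'   model on the log scale (exponentiated, so always positive).
#' @param detections_per_day Mean detections emitted on a present day
#'   (must be at least 2 so the presence rule can recover the day).
#' @param noise_detection_prob Probability that an absent day emits one
#'   isolated (non-qualifying) detection.
#' @param monitor_meanlog,monitor_sdlog Log-normal monitoring-duration
#'   parameters (days).
#' @param min_monitor_days Shortest monitoring window generated.
#' @param length_center Centring length in cm.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals = 32,
                       study_start = as.Date("2015-01-01"),
                       study_end = as.Date("2019-12-31"),
                       true_alpha = c(-1.0, -1.2, -0.015),
                       true_mu = c(0.5, 2.28, -0.33, 0.03),
                       true_sigma = c(0.3, 0.5, 0.3, 0.1),
                       prop_male = 0.4,
                       length_mean = 210, length_sd = 30,
                       length_min = 160, length_max = 280,
                       unknown_sex_count = 1,
                       temp_mean = 25.5, temp_amplitude = 3.2,
                       temp_phase_day = 240, temp_noise_sd = 0.6,
                       chl_log_mean = -0.8, chl_amplitude = 0.5,
                       chl_phase_day = 60, chl_noise_sd = 0.3,
                       detections_per_day = 12,
                       noise_detection_prob = 0.15,
                       monitor_meanlog = log(200), monitor_sdlog = 0.6,
                       min_monitor_days = 45,
                       length_center = 220) {
  cfg <- list(n_individuals = n_individuals, study_start = study_start,
              study_end = study_end, true_alpha = true_alpha,
              true_mu = true_mu, true_sigma = true_sigma,
              prop_male = prop_male, length_mean = length_mean,
              length_sd = length_sd, length_min = length_min,
              length_max = length_max, unknown_sex_count = unknown_sex_count,
              temp_mean = temp_mean, temp_amplitude = temp_amplitude,
              temp_phase_day = temp_phase_day, temp_noise_sd = temp_noise_sd,
              chl_log_mean = chl_log_mean, chl_amplitude = chl_amplitude,
              chl_phase_day = chl_phase_day, chl_noise_sd = chl_noise_sd,
              detections_per_day = detections_per_day,
              noise_detection_prob = noise_detection_prob,
              monitor_meanlog = monitor_meanlog,
              monitor_sdlog = monitor_sdlog,
              min_monitor_days = min_monitor_days,
              length_center = length_center)
  stopifnot(length(cfg$true_alpha) == 3, length(cfg$true_mu) == 4,
            length(cfg$true_sigma) == 4, all(cfg$true_sigma >= 0),
            cfg$prop_male >= 0, cfg$prop_male <= 1,
            cfg$unknown_sex_count >= 0,
            cfg$unknown_sex_count <= cfg$n_individuals,
            cfg$temp_noise_sd > 0, cfg$chl_noise_sd > 0,
            as.integer(cfg$study_end - cfg$study_start) + 1 >= 30,
            cfg$min_monitor_days >= 30)
  if (cfg$detections_per_day < 2) {
    rlang::abort("detections_per_day must be >= 2: a present day needs at least two clustered detections to round-trip through the presence rule.")
  }
  structure(cfg, class = "sim_config")
}

life_stage <- function(sex, length_cm) {
  # approximate maturity bands: males mature ~157-226 cm, females ~180-230 cm
  lo <- ifelse(sex == "male", 157, 180)
  hi <- ifelse(sex == "male", 226, 230)
  dplyr::case_when(length_cm < lo ~ "juvenile",
                   length_cm <= hi ~ "sub-adult",
                   TRUE ~ "adult")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a tagged cohort from the generative occurrence model
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return A list with `individuals` (metadata table, sex reported as
#'   `"unknown"` for the unrecorded individuals), `environment` (daily
#'   temperature and chlorophyll), `presence` (per individual-day Bernoulli
#'   presence over each monitoring window), and `truth` (the generating
#'   parameters, including each individual's true sex and slopes).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  cfg <- config
  withr::with_seed(seed, {
    dates <- seq(cfg$study_start, cfg$study_end, by = "day")
    tt <- as.POSIXlt(dates)$yday + 1
    environment <- tibble::tibble(
      date = dates,
      temperature_c = cfg$temp_mean +
        cfg$temp_amplitude * cos(2 * pi * (tt - cfg$temp_phase_day) / 365) +
        stats::rnorm(length(tt), 0, cfg$temp_noise_sd),
      chlorophyll = exp(cfg$chl_log_mean +
                          cfg$chl_amplitude * cos(2 * pi * (tt - cfg$chl_phase_day) / 365) +
                          stats::rnorm(length(tt), 0, cfg$chl_noise_sd))
    )
    covars <- build_covariates(environment)
    X <- as.matrix(covars[, covariate_cols()])

    I <- cfg$n_individuals
    tag_id <- sprintf("BS%02d", seq_len(I))
    sex_true <- ifelse(stats::runif(I) < cfg$prop_male, "male", "female")
    length_cm <- round(rtrunc_norm(I, cfg$length_mean, cfg$length_sd,
                                   cfg$length_min, cfg$length_max))
    unknown <- if (cfg$unknown_sex_count > 0) {
      sample.int(I, cfg$unknown_sex_count)
    } else integer(0)
    sex_reported <- sex_true
    sex_reported[unknown] <- "unknown"

    dur <- pmax(cfg$min_monitor_days,
                round(stats::rlnorm(I, cfg$monitor_meanlog, cfg$monitor_sdlog)))
    dur <- pmin(dur, length(dates))
    start <- vapply(dur, function(d) sample.int(length(dates) - d + 1, 1), 1L)

    beta <- vapply(1:4, function(j) {
      stats::rnorm(I, cfg$true_mu[j], cfg$true_sigma[j])
    }, numeric(I))
    if (I == 1) beta <- matrix(beta, nrow = 1)
    rownames(beta) <- tag_id
    male <- as.integer(sex_true == "male")
    beta0 <- cfg$true_alpha[1] + cfg$true_alpha[2] * male +
      cfg$true_alpha[3] * (length_cm - cfg$length_center)

    presence <- purrr::map(seq_len(I), function(i) {
      idx <- start[i]:(start[i] + dur[i] - 1)
      eta <- beta0[i] + as.vector(X[idx, , drop = FALSE] %*% beta[i, ])
      tibble::tibble(tag_id = tag_id[i], date = dates[idx],
                     present = stats::rbinom(length(idx), 1, stats::plogis(eta)))
    }) |>
      purrr::list_rbind()

    individuals <- tibble::tibble(
      tag_id = tag_id, sex = sex_reported, length_cm = length_cm,
      stage = life_stage(sex_true, length_cm), tag_date = dates[start]
    )
    truth <- list(alpha = cfg$true_alpha, mu = cfg$true_mu,
                  sigma = cfg$true_sigma, beta = beta,
                  sex_true = stats::setNames(sex_true, tag_id))
    list(individuals = individuals, environment = environment,
         presence = presence, truth = truth)
  })
}

#' Expand a daily presence series into a raw detection stream
#'
#' The inverse of the presence rule: each present day emits a cluster of at
#' least two detections whose consecutive gaps are all strictly under 15
#' minutes; an absent day emits either nothing or a single isolated
#' detection (which the rule cannot promote to presence).  Round-tripping
#' through [daily_presence()] on the same day grid therefore recovers the
#' input series exactly.
#'
#' @param presence A tibble with `tag_id`, `date`, `present`.
#' @param config A [sim_config()] (supplies the detection intensity).
#' @param seed Integer seed.
#'
#' @return A detection tibble: `tag_id`, `receiver_id`, `timestamp` (UTC).
#' @export
explode_to_detections <- function(presence, config = sim_config(), seed = 1) {
  cfg <- config
  receivers <- sprintf("CP%02d", 1:16)
  withr::with_seed(seed, {
    pres <- presence[presence$present == 1, ]
    n_det <- 2L + stats::rpois(nrow(pres), max(0, cfg$detections_per_day - 2))
    gaps <- split(stats::runif(sum(n_det - 1L), 60, 800),
                  rep(seq_len(nrow(pres)), n_det - 1L))
    offsets <- lapply(gaps, function(g) c(0, cumsum(g)))
    span <- vapply(offsets, max, numeric(1))
    t0 <- stats::runif(nrow(pres), 0, 86400 - span - 1)
    pres_det <- tibble::tibble(
      tag_id = rep(pres$tag_id, n_det),
      timestamp = as.POSIXct(rep(pres$date, n_det), tz = "UTC") +
        rep(t0, n_det) + unlist(offsets, use.names = FALSE)
    )
    abs_rows <- presence[presence$present == 0, ]
    noisy <- stats::runif(nrow(abs_rows)) < cfg$noise_detection_prob
    abs_det <- tibble::tibble(
      tag_id = abs_rows$tag_id[noisy],
      timestamp = as.POSIXct(abs_rows$date[noisy], tz = "UTC") +
        stats::runif(sum(noisy), 0, 86399)
    )
    out <- dplyr::bind_rows(pres_det, abs_det)
    out$receiver_id <- sample(receivers, nrow(out), replace = TRUE)
    dplyr::arrange(out[, c("tag_id", "receiver_id", "timestamp")],
                   .data$tag_id, .data$timestamp)
  })
}
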