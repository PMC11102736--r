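# shared fixtures, all generated in code

make_detections <- function(tag, times, day = "2017-03-01",
                            receiver = "CP01") {
  tibble::tibble(
    tag_id = tag,
    receiver_id = receiver,
    timestamp = as.POSIXct(paste(day, times), tz = "UTC")
  )
}

# a bare model table for likelihood / binning tests
make_model_table <- function(tag_id, dates, present, X, male_indicator,
                             sex_known, length_centered) {
  tibble::tibble(
    tag_id = tag_id, date = dates, present = present,
    x1_star = X[, 1], x2_star = X[, 2], x3_star = X[, 3], x4_star = X[, 4],
    male_indicator = male_indicator, sex_known = sex_known,
    length_centered = length_centered
  )
}

# hand-built occ_fit with known draws, bypassing MCMC, for curve and
# envelope arithmetic tests
fake_fit <- function(n_ind = 2, n_day = 30, n_draw = 50, seed = 42,
                     alpha = NULL, mu = NULL, sigma = NULL,
                     constant = FALSE) {
  withr::with_seed(seed, {
    tags <- sprintf("T%02d", seq_len(n_ind))
    dates <- seq(as.Date("2017-01-01"), by = "day", length.out = n_day)
    male <- rep_len(c(0L, 1L), n_ind)
    lenc <- round(stats::runif(n_ind, -60, 60))
    X <- cbind(cos(2 * pi * seq_len(n_day) / 365),
               sin(2 * pi * seq_len(n_day) / 365),
               stats::rnorm(n_day, -0.8, 0.3),
               stats::rnorm(n_day, -2.5, 1))
    rnd <- function(centre, sd) {
      if (constant) rep(centre, n_draw) else stats::rnorm(n_draw, centre, sd)
    }
    draws <- tibble::tibble(
      alpha0 = rnd(if (is.null(alpha)) 0 else alpha[1], 0.3),
      alpha1 = rnd(if (is.null(alpha)) -1 else alpha[2], 0.3),
      alpha2 = rnd(if (is.null(alpha)) -0.01 else alpha[3], 0.005)
    )
    for (j in 1:4) {
      draws[[paste0("mu[", j, "]")]] <-
        rnd(if (is.null(mu)) c(0.4, 2, -0.3, 0)[j] else mu[j], 0.2)
      draws[[paste0("sigma[", j, "]")]] <-
        abs(rnd(if (is.null(sigma)) 0.4 else sigma[j], 0.1))
    }
    draws$pi <- stats::runif(n_draw)
    tab <- list()
    for (k in seq_len(n_ind)) {
      for (j in 1:4) {
        draws[[paste0("beta[", k, ",", j, "]")]] <-
          draws[[paste0("mu[", j, "]")]] +
          (if (constant) 0 else stats::rnorm(n_draw, 0, 0.2))
      }
      draws[[paste0("beta0[", k, "]")]] <-
        draws$alpha0 + draws$alpha1 * male[k] + draws$alpha2 * lenc[k]
      draws[[paste0("z[", k, "]")]] <- stats::rbinom(n_draw, 1, draws$pi)
      eta <- drop(X %*% c(0.4, 2, -0.3, 0))
      tab[[k]] <- make_model_table(tags[k], dates,
                                   stats::rbinom(n_day, 1, stats::plogis(eta)),
                                   X, male[k], TRUE, lenc[k])
    }
    draws$.chain <- 1L
    draws$.iteration <- seq_len(n_draw)
    idx <- tibble::tibble(tag_id = tags, male_indicator = male,
                          sex_known = TRUE, length_centered = lenc,
                          i = seq_len(n_ind))
    structure(
      list(draws = draws, index = idx, data = purrr::list_rbind(tab),
           diagnostics = NULL, flagged = character(0),
           priors = occ_priors(), sampler = occ_sampler(), seed = seed,
           rhat_threshold = 1.01),
      class = "occ_fit"
    )
  })
}

# independent per-observation Bernoulli likelihood with explicit
# two-branch sex enumeration (probability-scale products)
brute_force_loglik <- function(tab, params) {
  total <- 0
  for (tag in unique(tab$tag_id)) {
    rows <- tab[tab$tag_id == tag, ]
    X <- as.matrix(rows[, paste0("x", 1:4, "_star")])
    lik_branch <- function(male) {
      eta <- params$alpha[1] + params$alpha[2] * male +
        params$alpha[3] * rows$length_centered[1] +
        drop(X %*% params$beta[tag, ])
      p <- 1 / (1 + exp(-eta))
      prod(ifelse(rows$present == 1, p, 1 - p))
    }
    if (rows$sex_known[1]) {
      total <- total + log(lik_branch(rows$male_indicator[1]))
    } else {
      total <- total + log(params$pi * lik_branch(1) +
                             (1 - params$pi) * lik_branch(0))
    }
  }
  total
}

# small simulated cohort settings for fast MCMC smoke tests
tiny_sim <- function(n = 4, days = 120, ...) {
  sim_config(
    n_individuals = n,
    study_start = as.Date("2017-01-01"),
    study_end = as.Date("2017-01-01") + days + 60,
    monitor_meanlog = log(days), monitor_sdlog = 0.1,
    detections_per_day = 4,
    ...
  )
}

quick_sampler <- function(chains = 2, iter = 600, warmup = 300) {
  occ_sampler(chains = chains, iter = iter, warmup = warmup)
}
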