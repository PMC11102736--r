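test_that("log-likelihood at a zeroed predictor is log(0.5) per observation", {
  tab <- make_model_table("A", as.Date("2017-03-01"), 1L,
                          matrix(0, 1, 4), 0L, TRUE, 0)
  params <- list(alpha = c(0, 0, 0), beta = matrix(0, 1, 4,
                                                   dimnames = list("A", NULL)))
  expect_equal(log_lik_occurrence(tab, params), log(0.5))
})

test_that("a degenerate mixture weight reduces to the corresponding sex branch", {
  set.seed(8)
  X <- matrix(rnorm(20), 5, 4)
  y <- rbinom(5, 1, 0.5)
  unk <- make_model_table("U", as.Date("2017-03-01") + 0:4, y, X,
                          NA_integer_, FALSE, -10)
  male <- make_model_table("U", as.Date("2017-03-01") + 0:4, y, X,
                           1L, TRUE, -10)
  params <- list(alpha = c(0.2, -0.9, 0.01),
                 beta = matrix(rnorm(4), 1, 4, dimnames = list("U", NULL)))
  expect_equal(log_lik_occurrence(unk, c(params, pi = 1)),
               log_lik_occurrence(male, params))
  female <- make_model_table("U", as.Date("2017-03-01") + 0:4, y, X,
                             0L, TRUE, -10)
  expect_equal(log_lik_occurrence(unk, c(params, pi = 0)),
               log_lik_occurrence(female, params))
})

test_that("posterior summaries are equal-tailed quantile intervals", {
  const <- data.frame(theta = rep(1.7, 100))
  s <- posterior_summary(const)
  expect_equal(s$lower, 1.7)
  expect_equal(s$upper, 1.7)
  expect_equal(s$mean, 1.7)

  set.seed(2)
  z <- data.frame(z = rnorm(10000))
  sz <- posterior_summary(z)
  expect_equal(sz$lower, -1.96, tolerance = 0.04)
  expect_equal(sz$upper, 1.96, tolerance = 0.04)

  expect_error(posterior_summary(z, level = 1.2), "level")
})

test_that("a small synthetic fit is reproducible and internally consistent", {
  sim <- simulate_cohort(tiny_sim(n = 4, days = 100), seed = 5)
  cv <- build_covariates(sim$environment)
  tab <- assemble_model_table(sim$presence, cv, sim$individuals,
                              min_duration_days = 30)
  # short chains may legitimately trip the Rhat flag; that surfacing is the
  # contract under test elsewhere, not here
  fit <- suppressWarnings(
    fit_occurrence(tab, sampler = quick_sampler(chains = 2, iter = 500,
                                                warmup = 250), seed = 9))
  expect_s3_class(fit, "occ_fit")
  expect_equal(nrow(fit$draws), 2 * 250)

  # derived intercepts reproduce the fixed-effect relation draw by draw
  k <- which(fit$index$sex_known)[1]
  b0 <- fit$draws[[paste0("beta0[", k, "]")]]
  rebuilt <- fit$draws$alpha0 +
    fit$draws$alpha1 * fit$index$male_indicator[k] +
    fit$draws$alpha2 * fit$index$length_centered[k]
  expect_lt(max(abs(b0 - rebuilt)), 1e-10)

  # the mixture weight stays a probability
  expect_true(all(fit$draws$pi >= 0 & fit$draws$pi <= 1))
  expect_true(all(as.matrix(fit$draws[, paste0("sigma[", 1:4, "]")]) > 0))

  # diagnostics cover every monitored continuous parameter
  expect_true(all(c("alpha0", "mu[2]", "sigma[4]", "pi",
                    "beta[1,1]", "beta0[4]") %in%
                    fit$diagnostics$parameter))

  # bit-reproducibility given the same seed and config
  fit2 <- fit_occurrence(tab, sampler = quick_sampler(chains = 2, iter = 500,
                                                      warmup = 250),
                         seed = 9, diagnostics = FALSE)
  expect_equal(fit$draws, fit2$draws)

  # tidy/glance surfaces
  td <- tidy(fit)
  expect_equal(nrow(td), 12)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  g <- glance(fit)
  expect_equal(g$n_individuals, 4L)
  expect_equal(g$n_draws, 500L)
})

test_that("prior-predictive presence frequencies are not degenerate", {
  set.seed(14)
  pr <- occ_priors()
  freqs <- replicate(20, {
    mu <- rnorm(4, 0, pr$mu_sd)
    sigma <- abs(rnorm(4, 0, pr$sigma_scale))
    cfg <- tiny_sim(n = 3, days = 150,
                    true_alpha = c(rnorm(1, 0, pr$alpha0_sd),
                                   rnorm(1, 0, pr$alpha1_sd),
                                   rnorm(1, 0, pr$alpha2_sd)),
                    true_mu = mu, true_sigma = sigma)
    sim <- simulate_cohort(cfg, seed = sample.int(1e6, 1))
    mean(sim$presence$present)
  })
  expect_true(all(freqs >= 0 & freqs <= 1))
  expect_gt(stats::sd(freqs), 0.01)        # spans a range of frequencies
  expect_true(any(freqs > 0.05 & freqs < 0.95))   # and is not all-saturated
})

test_that("centred and non-centred slope parameterizations agree", {
  sim <- simulate_cohort(tiny_sim(n = 4, days = 100), seed = 5)
  cv <- build_covariates(sim$environment)
  tab <- assemble_model_table(sim$presence, cv, sim$individuals,
                              min_duration_days = 30)
  pars <- c("alpha1", paste0("mu[", 1:4, "]"))
  fits <- lapply(c("centered", "noncentered"), function(pz) {
    f <- suppressWarnings(
      fit_occurrence(tab, sampler = quick_sampler(chains = 2, iter = 700,
                                                  warmup = 350),
                     seed = 17, parameterization = pz, diagnostics = FALSE))
    s <- posterior_summary(f, pars = pars)
    s[match(pars, s$parameter), ]
  })
  # same posterior up to Monte-Carlo error: means within 3 pooled MCSE-ish
  # bounds (conservative: treat draws as weakly dependent)
  tol <- 3 * sqrt(fits[[1]]$sd^2 + fits[[2]]$sd^2) / sqrt(50)
  expect_true(all(abs(fits[[1]]$mean - fits[[2]]$mean) < tol))
})
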