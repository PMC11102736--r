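covs_for <- function(fit) {
  # rebuild a covariate table matching the fake fit's design columns
  tab <- fit$data[fit$data$tag_id == fit$index$tag_id[1], ]
  out <- tibble::tibble(date = tab$date)
  for (j in 1:4) out[[paste0("x", j, "_star")]] <- tab[[paste0("x", j, "_star")]]
  out
}

test_that("all-zero draws give a flat 0.5 curve with a zero-width band", {
  fit <- fake_fit(n_ind = 2, n_day = 25, n_draw = 30,
                  alpha = c(0, 0, 0), mu = rep(0, 4), sigma = rep(0, 4),
                  constant = TRUE)
  cv <- covs_for(fit)
  cv[, paste0("x", 1:4, "_star")] <- 0
  cur <- individual_curve(fit, "T01", cv)
  expect_true(all(cur$p_mean == 0.5))
  expect_true(all(cur$p_lower == 0.5 & cur$p_upper == 0.5))
})

test_that("a single posterior draw reproduces the closed-form logistic curve", {
  fit <- fake_fit(n_ind = 2, n_day = 25, n_draw = 1)
  cv <- covs_for(fit)
  cur <- individual_curve(fit, "T02", cv)
  X <- as.matrix(cv[, paste0("x", 1:4, "_star")])
  b <- as.numeric(fit$draws[1, paste0("beta[2,", 1:4, "]")])
  b0 <- fit$draws[["beta0[2]"]][1]
  expect_equal(cur$p_mean, plogis(b0 + drop(X %*% b)))
  expect_equal(cur$p_lower, cur$p_mean)

  expect_error(individual_curve(fit, "nope", cv), "Unknown tag_id")
})

test_that("an all-negative male effect puts the male curve below the female", {
  fit <- fake_fit(n_ind = 2, n_day = 40, n_draw = 60, alpha = c(0, -1, 0))
  stopifnot(all(fit$draws$alpha1 < 0))
  cv <- covs_for(fit)
  f <- expected_curve(fit, "female", 200, cv, seed = 4)
  m <- expected_curve(fit, "male", 200, cv, seed = 4)
  expect_true(all(m$p_mean < f$p_mean))

  d <- sex_difference_curve(fit, 200, cv, seed = 4)
  expect_true(all(d$p_mean > 0))            # female minus male, pct points
  expect_equal(d$p_mean, 100 * (f$p_mean - m$p_mean))
})

test_that("curves respect probability bounds and interval ordering", {
  fit <- fake_fit(n_ind = 3, n_day = 50, n_draw = 80, seed = 77)
  cv <- covs_for(fit)
  for (cur in list(individual_curve(fit, "T01", cv),
                   expected_curve(fit, "male", 240, cv, seed = 2),
                   marginal_population_curve(fit, cv, seed = 2))) {
    expect_true(all(cur$p_lower <= cur$p_mean + 1e-12))
    expect_true(all(cur$p_mean <= cur$p_upper + 1e-12))
    expect_true(all(cur$p_lower >= 0 & cur$p_upper <= 1))
  }
})

test_that("a one-member cohort's marginal curve is that member's expected curve", {
  fit <- fake_fit(n_ind = 2, n_day = 30, n_draw = 40)
  cv <- covs_for(fit)
  one <- tibble::tibble(sex = "female", length_cm = 210)
  mg <- marginal_population_curve(fit, cv, individuals = one, seed = 6)
  ex <- expected_curve(fit, "female", 210, cv, seed = 6)
  expect_equal(mg$p_mean, ex$p_mean)
  expect_equal(mg$p_upper, ex$p_upper)
})

test_that("a two-member marginal curve averages the per-draw member curves", {
  fit <- fake_fit(n_ind = 2, n_day = 30, n_draw = 40)
  cv <- covs_for(fit)
  two <- tibble::tibble(sex = c("female", "male"), length_cm = c(180, 250))
  mg <- marginal_population_curve(fit, cv, individuals = two, seed = 6)

  # direct recomputation: same slope-draw stream, plain logistic arithmetic
  X <- as.matrix(cv[, paste0("x", 1:4, "_star")])
  D <- nrow(fit$draws)
  mu <- as.matrix(fit$draws[, paste0("mu[", 1:4, "]")])
  sg <- as.matrix(fit$draws[, paste0("sigma[", 1:4, "]")])
  P <- withr::with_seed(6, {
    b1 <- mu + sg * matrix(rnorm(D * 4), D, 4)
    p1 <- plogis(X %*% t(b1) +
                   matrix(fit$draws$alpha0 + fit$draws$alpha2 * (180 - 220),
                          nrow(X), D, byrow = TRUE))
    b2 <- mu + sg * matrix(rnorm(D * 4), D, 4)
    p2 <- plogis(X %*% t(b2) +
                   matrix(fit$draws$alpha0 + fit$draws$alpha1 +
                            fit$draws$alpha2 * (250 - 220),
                          nrow(X), D, byrow = TRUE))
    (p1 + p2) / 2
  })
  expect_equal(mg$p_mean, rowMeans(P))
})

test_that("wider population SD draws widen expected-curve bands", {
  narrow <- fake_fit(n_ind = 2, n_day = 40, n_draw = 120,
                     sigma = rep(0.1, 4), seed = 10)
  wide <- fake_fit(n_ind = 2, n_day = 40, n_draw = 120,
                   sigma = rep(1.2, 4), seed = 10)
  cv <- covs_for(narrow)
  bn <- expected_curve(narrow, "female", 200, cv, seed = 3)
  bw <- expected_curve(wide, "female", 200, cv, seed = 3)
  expect_gt(mean(bw$p_upper - bw$p_lower), mean(bn$p_upper - bn$p_lower))
})

test_that("monthly polar summaries average by calendar month", {
  dates <- seq(as.Date("2017-01-01"), as.Date("2017-12-31"), 1)
  env <- tibble::tibble(date = dates, temperature_c = 25, chlorophyll = 0.5)
  flat <- structure(tibble::tibble(date = dates, p_mean = 0.4,
                                   p_lower = 0.3, p_upper = 0.5),
                    class = c("occ_curve", class(tibble::tibble())))
  ps <- polar_summary(flat, env)
  expect_equal(nrow(ps), 12)
  expect_true(all(ps$p_mean == 0.4))

  wav <- flat
  wav$p_mean <- 0.5 + 0.4 * sin(2 * pi * seq_along(dates) / 365)
  ps2 <- polar_summary(wav, env)
  hand <- tapply(wav$p_mean, format(dates, "%b"), mean)
  expect_equal(ps2$p_mean, unname(as.numeric(hand[as.character(ps2$month)])))
})
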