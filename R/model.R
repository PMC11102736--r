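#' Prior configuration for the occurrence model
#'
#' Defaults: Normal(0, 2.5) for the baseline intercept, the male effect and
#' the population slope means; Normal(0, 1) for the per-cm length effect
#' (length is in cm, so its coefficient lives on a small scale);
#' Half-Normal(1) for the between-individual slope SDs; Uniform(0, 1) for
#' the probability that the unrecorded-sex individual is male.  All scales
#' are standard deviations.
#'
#' @param alpha0_sd,alpha1_sd,alpha2_sd Prior SDs of the intercept terms.
#' @param mu_sd Prior SD of each population-level slope mean.
#' @param sigma_scale Scale of the Half-Normal prior on each slope SD.
#'
#' @return A list of class `"occ_priors"`.
#' @export
occ_priors <- function(alpha0_sd = 2.5, alpha1_sd = 2.5, alpha2_sd = 1,
                       mu_sd = 2.5, sigma_scale = 1) {
  stopifnot(alpha0_sd > 0, alpha1_sd > 0, alpha2_sd > 0,
            mu_sd > 0, sigma_scale > 0)
  structure(list(alpha0_sd = alpha0_sd, alpha1_sd = alpha1_sd,
                 alpha2_sd = alpha2_sd, mu_sd = mu_sd,
                 sigma_scale = sigma_scale),
            class = "occ_priors")
}

#' Sampler configuration
#'
#' `iter` is the total number of MCMC iterations per chain, of which the
#' first `warmup` are discarded (adaptation plus burn-in).  Two presets are
#' provided: `"default"` (4 chains of 2,000 with 1,000 warmup) and
#' `"long"` (3 chains of 4,000 with half used as warmup).
#'
#' @param chains Number of chains.
#' @param iter Total iterations per chain.
#' @param warmup Iterations discarded per chain (includes adaptation).
#' @param preset Optional preset name overriding the other arguments:
#'   `"default"` or `"long"`.
#'
#' @return A list of class `"occ_sampler"`.
#' @export
occ_sampler <- function(chains = 4, iter = 2000, warmup = 1000,
                        preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("default", "long"))
    if (preset == "default") {
      chains <- 4; iter <- 2000; warmup <- 1000
    } else {
      chains <- 3; iter <- 4000; warmup <- 2000
    }
  }
  stopifnot(chains >= 1, iter > warmup, warmup >= 100)
  structure(list(chains = chains, iter = iter, warmup = warmup),
            class = "occ_sampler")
}

occ_jags_model <- function(priors, noncentered = FALSE) {
  prec <- function(sd) formatC(1 / sd^2, format = "g", digits = 12)
  slope_block <- if (noncentered) {
    "zb[i, j] ~ dnorm(0, 1)
      beta[i, j] <- mu[j] + sigma[j] * zb[i, j]"
  } else {
    "beta[i, j] ~ dnorm(mu[j], tau_beta[j])"
  }
  paste0("
model {
  for (i in 1:I) {
    z[i] ~ dbern(pi)
    msex[i] <- known[i] * male[i] + (1 - known[i]) * z[i]
    beta0[i] <- alpha0 + alpha1 * msex[i] + alpha2 * lenc[i]
    for (j in 1:J) {
      ", slope_block, "
    }
  }
  for (n in 1:N) {
    logit(p[n]) <- beta0[ind[n]] + inprod(beta[ind[n], 1:J], X[n, 1:J])
    y[n] ~ dbern(p[n])
  }
  alpha0 ~ dnorm(0, ", prec(priors$alpha0_sd), ")
  alpha1 ~ dnorm(0, ", prec(priors$alpha1_sd), ")
  alpha2 ~ dnorm(0, ", prec(priors$alpha2_sd), ")
  for (j in 1:J) {
    mu[j] ~ dnorm(0, ", prec(priors$mu_sd), ")
    sigma[j] ~ dnorm(0, ", prec(priors$sigma_scale), ") T(0,)
    tau_beta[j] <- 1 / pow(sigma[j], 2)
  }
  pi ~ dbeta(1, 1)
}
")
}

occ_index <- function(model_table) {
  idx <- model_table |>
    dplyr::distinct(.data$tag_id, .data$male_indicator, .data$sex_known,
                    .data$length_centered) |>
    dplyr::arrange(.data$tag_id)
  if (anyDuplicated(idx$tag_id)) {
    rlang::abort("Inconsistent sex/length within a tag_id in the model table.")
  }
  idx$i <- seq_len(nrow(idx))
  idx
}

covariate_cols <- function() paste0("x", 1:4, "_star")

covariate_labels <- function() c("cos", "sin", "logchl", "temperature")

#' Fit the hierarchical occurrence model
#'
#' Daily presence of each individual is Bernoulli with
#' \deqn{\mathrm{logit}(p_{i,t}) = \beta_{0,i} + \sum_{j=1}^{4} \beta_{j,i} x^{*}_{j,t},}
#' where the intercept is a fixed-effect function of sex and centred length,
#' \eqn{\beta_{0,i} = \alpha_0 + \alpha_1 \mathrm{male}_i + \alpha_2
#' (\mathrm{length}_i - 220)}, and each individual's slopes are drawn from
#' population distributions \eqn{\beta_{j,i} \sim N(\mu_j, \sigma_j)}.  For
#' an individual whose sex was not recorded, a parameter \eqn{\pi} gives the
#' probability that it is male and its whole series is marginalized over the
#' two sex branches (sex is a single latent attribute, sampled per
#' iteration, not an independent coin per day).
#'
#' Sampling is by Gibbs/slice MCMC (JAGS with its `glm` samplers).  The run
#' is reproducible bit-for-bit given `seed` and the sampler configuration.
#' Convergence is summarised by rank-normalized split-\eqn{\hat R} and bulk
#' and tail effective sample sizes for every monitored parameter; any
#' \eqn{\hat R} above `rhat_threshold` raises a warning.
#'
#' @param model_table Output of [assemble_model_table()].
#' @param priors An [occ_priors()] configuration.
#' @param sampler An [occ_sampler()] configuration.
#' @param seed Integer seed controlling every chain's RNG.
#' @param parameterization `"centered"` (default) keeps the slope layer in
#'   its natural form, for which the backend's block samplers give the best
#'   wall-clock throughput; `"noncentered"` rewrites each slope as
#'   `mu + sigma * z` with standard-normal `z`, which mixes far better when
#'   a between-individual SD sits near zero (the hierarchical funnel) at a
#'   higher per-iteration cost.  Both target the identical posterior.
#' @param rhat_threshold Convergence flag threshold.  Default 1.01.
#' @param diagnostics Compute per-parameter convergence diagnostics.
#'   Default `TRUE`.
#' @param quiet Suppress JAGS progress output.  Default `TRUE`.
#'
#' @return An object of class `"occ_fit"`: a list with `draws` (a tibble of
#'   posterior draws, one row per retained iteration, with `.chain` and
#'   `.iteration` columns), `index` (tag to model-index map with the
#'   intercept design), `data` (the model table), `diagnostics`,
#'   `priors`, `sampler`, `seed`.
#' @export
fit_occurrence <- function(model_table, priors = occ_priors(),
                           sampler = occ_sampler(), seed = 1,
                           parameterization = c("centered", "noncentered"),
                           rhat_threshold = 1.01, diagnostics = TRUE,
                           quiet = TRUE) {
  parameterization <- match.arg(parameterization)
  idx <- occ_index(model_table)
  ind <- match(model_table$tag_id, idx$tag_id)
  X <- as.matrix(model_table[, covariate_cols()])
  dat <- list(
    y = as.integer(model_table$present),
    N = nrow(model_table),
    ind = ind,
    X = X,
    I = nrow(idx),
    J = 4L,
    male = ifelse(idx$sex_known, idx$male_indicator, 0L),
    known = as.integer(idx$sex_known),
    lenc = idx$length_centered
  )
  rjags::load.module("glm", quiet = TRUE)
  inits <- lapply(seq_len(sampler$chains), function(ch) {
    list(.RNG.name = "base::Wichmann-Hill",
         .RNG.seed = (as.integer(seed) * 101L + ch) %% .Machine$integer.max)
  })
  n_adapt <- min(500L, floor(sampler$warmup / 2))
  n_burn <- sampler$warmup - n_adapt
  model_code <- occ_jags_model(priors,
                               noncentered = parameterization == "noncentered")
  jm <- rjags::jags.model(textConnection(model_code), data = dat,
                          inits = inits, n.chains = sampler$chains,
                          n.adapt = n_adapt, quiet = quiet)
  if (n_burn > 0) {
    update(jm, n.iter = n_burn, progress.bar = if (quiet) "none" else "text")
  }
  monitors <- c("alpha0", "alpha1", "alpha2", "mu", "sigma", "pi",
                "beta", "beta0", "z")
  samp <- rjags::coda.samples(jm, variable.names = monitors,
                              n.iter = sampler$iter - sampler$warmup,
                              progress.bar = if (quiet) "none" else "text")
  draws <- purrr::imap(samp, function(ch, k) {
    m <- tibble::as_tibble(as.matrix(ch), .name_repair = "minimal")
    m$.chain <- as.integer(k)
    m$.iteration <- seq_len(nrow(m))
    m
  }) |>
    purrr::list_rbind()
  diag_tbl <- NULL
  flagged <- character(0)
  if (diagnostics) {
    skip <- grep("^(z|zb)\\[", coda::varnames(samp), value = TRUE)
    diag_tbl <- occ_diagnostics(samp, skip = skip)
    flagged <- diag_tbl$parameter[!is.na(diag_tbl$rhat) &
                                    diag_tbl$rhat > rhat_threshold]
    if (length(flagged)) {
      rlang::warn(paste0("Rhat above ", rhat_threshold, " for: ",
                         paste(flagged, collapse = ", ")))
    }
  }
  structure(
    list(draws = draws, index = idx, data = model_table,
         diagnostics = diag_tbl, flagged = flagged,
         priors = priors, sampler = sampler, seed = seed,
         parameterization = parameterization,
         rhat_threshold = rhat_threshold),
    class = "occ_fit"
  )
}

# rank-normalized split-chain Rhat and bulk/tail effective sample sizes
rank_normalize <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (length(x) + 1 / 4))
}

split_chain_matrix <- function(m) {
  n <- floor(nrow(m) / 2)
  cbind(m[seq_len(n), , drop = FALSE],
        m[(nrow(m) - n + 1):nrow(m), , drop = FALSE])
}

rhat_split <- function(m) {
  sc <- split_chain_matrix(m)
  if (stats::sd(as.vector(sc)) == 0) return(NA_real_)
  z <- matrix(rank_normalize(as.vector(sc)), nrow = nrow(sc))
  n <- nrow(z)
  W <- mean(apply(z, 2, stats::var))
  B <- n * stats::var(colMeans(z))
  sqrt((n - 1) / n + B / (W * n))
}

ess_of <- function(m) {
  ml <- coda::as.mcmc.list(lapply(seq_len(ncol(m)),
                                  function(k) coda::as.mcmc(m[, k])))
  as.numeric(coda::effectiveSize(ml))
}

ess_bulk_tail <- function(m) {
  sc <- split_chain_matrix(m)
  if (stats::sd(as.vector(sc)) == 0) return(c(NA_real_, NA_real_))
  z <- matrix(rank_normalize(as.vector(sc)), nrow = nrow(sc))
  bulk <- ess_of(z)
  q <- stats::quantile(as.vector(sc), c(0.05, 0.95))
  t1 <- ess_of((sc <= q[1]) * 1)
  t2 <- ess_of((sc <= q[2]) * 1)
  c(bulk, min(t1, t2))
}

occ_diagnostics <- function(samp, skip = character(0)) {
  pars <- setdiff(coda::varnames(samp), skip)
  arr <- lapply(samp, as.matrix)
  rows <- lapply(pars, function(p) {
    m <- do.call(cbind, lapply(arr, function(a) a[, p]))
    bt <- ess_bulk_tail(m)
    tibble::tibble(parameter = p, rhat = rhat_split(m),
                   ess_bulk = bt[1], ess_tail = bt[2])
  })
  purrr::list_rbind(rows)
}

#' @export
print.occ_fit <- function(x, ...) {
  cat("Hierarchical Bernoulli occurrence model fit\n")
  cat("  individuals:", nrow(x$index),
      " observations:", nrow(x$data), "\n")
  cat("  chains:", x$sampler$chains,
      " kept draws/chain:", x$sampler$iter - x$sampler$warmup, "\n")
  if (!is.null(x$diagnostics)) {
    cat("  max Rhat:", round(max(x$diagnostics$rhat, na.rm = TRUE), 4),
        " min bulk ESS:", round(min(x$diagnostics$ess_bulk, na.rm = TRUE)), "\n")
  }
  if (length(x$flagged)) {
    cat("  ! convergence flagged for:", paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(x)))

bernoulli_loglik <- function(y, eta) {
  sum(y * eta - log1pexp(eta))
}

logsumexp2 <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(m)
  m + log(exp(a - m) + exp(b - m))
}

#' Joint log-likelihood at one parameter point
#'
#' Sums Bernoulli log-mass over all individual-days at
#' \eqn{p_{i,t} = \mathrm{logit}^{-1}(\beta_{0,i} + \sum_j \beta_{j,i}
#' x^*_{j,t})}.  For an individual with unrecorded sex the whole series is
#' marginalized jointly over the two sex branches:
#' \eqn{\log(\pi L_{male} + (1-\pi) L_{female})}, computed by log-sum-exp.
#'
#' @param model_table Output of [assemble_model_table()].
#' @param params A list with `alpha` (numeric 3-vector: baseline, male
#'   effect, per-cm length effect), `beta` (matrix of individual slopes,
#'   one row per individual with rownames = tag ids, 4 columns), and `pi`
#'   (scalar in `[0, 1]`; needed only if an unrecorded-sex individual is
#'   present).
#'
#' @return The joint log-likelihood (a single number).
#' @export
log_lik_occurrence <- function(model_table, params) {
  alpha <- params$alpha
  stopifnot(length(alpha) == 3)
  beta <- params$beta
  idx <- occ_index(model_table)
  if (is.null(rownames(beta))) {
    stopifnot(nrow(beta) == nrow(idx))
    rownames(beta) <- idx$tag_id
  }
  total <- 0
  for (k in seq_len(nrow(idx))) {
    tag <- idx$tag_id[k]
    rows <- model_table$tag_id == tag
    y <- model_table$present[rows]
    X <- as.matrix(model_table[rows, covariate_cols()])
    slope_part <- as.vector(X %*% beta[tag, ])
    base <- alpha[1] + alpha[3] * idx$length_centered[k]
    if (idx$sex_known[k]) {
      eta <- base + alpha[2] * idx$male_indicator[k] + slope_part
      if (any(!is.finite(eta))) {
        rlang::abort(paste0("Non-finite linear predictor for tag ", tag))
      }
      total <- total + bernoulli_loglik(y, eta)
    } else {
      pi <- params$pi
      if (is.null(pi)) rlang::abort("params$pi required: unrecorded-sex individual present.")
      stopifnot(pi >= 0, pi <= 1)
      eta_m <- base + alpha[2] + slope_part
      eta_f <- base + slope_part
      if (any(!is.finite(eta_m)) || any(!is.finite(eta_f))) {
        rlang::abort(paste0("Non-finite linear predictor for tag ", tag))
      }
      lm <- bernoulli_loglik(y, eta_m)
      lf <- bernoulli_loglik(y, eta_f)
      total <- total + logsumexp2(log(pi) + lm, log(1 - pi) + lf)
    }
  }
  total
}

#' Posterior means and equal-tailed credible intervals
#'
#' @param x An `occ_fit`, or a data frame / matrix of posterior draws
#'   (columns are parameters).
#' @param level Credible level in (0, 1).  Default 0.95.
#' @param pars Optional character vector restricting the parameters.
#'
#' @return A tibble with `parameter`, `mean`, `sd`, `lower`, `upper`.
#' @export
posterior_summary <- function(x, level = 0.95, pars = NULL) {
  if (level <= 0 || level >= 1) rlang::abort("level must be in (0, 1).")
  draws <- if (inherits(x, "occ_fit")) x$draws else tibble::as_tibble(as.data.frame(x))
  if (nrow(draws) == 0) rlang::abort("No draws.")
  keep <- setdiff(names(draws), c(".chain", ".iteration"))
  if (!is.null(pars)) keep <- intersect(keep, pars)
  a <- (1 - level) / 2
  purrr::map(keep, function(p) {
    v <- draws[[p]]
    tibble::tibble(parameter = p, mean = mean(v), sd = stats::sd(v),
                   lower = unname(stats::quantile(v, a)),
                   upper = unname(stats::quantile(v, 1 - a)))
  }) |>
    purrr::list_rbind()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the population-level posterior
#'
#' @param x An `occ_fit`.
#' @param level Credible level for the intervals.
#' @param ... Unused.
#'
#' @return A tibble with one row per population-level parameter: `term`,
#'   `estimate`, `std.error`, `conf.low`, `conf.high`, plus `rhat` and
#'   `ess_bulk` when diagnostics were computed.
#' @method tidy occ_fit
#' @export
tidy.occ_fit <- function(x, level = 0.95, ...) {
  labs <- covariate_labels()
  pars <- c("alpha0", "alpha1", "alpha2",
            paste0("mu[", 1:4, "]"), paste0("sigma[", 1:4, "]"), "pi")
  terms <- c("alpha0", "alpha1_male", "alpha2_length",
             paste0("mu_", labs), paste0("sigma_", labs), "pi")
  s <- posterior_summary(x, level = level, pars = pars)
  s <- s[match(pars, s$parameter), ]
  out <- tibble::tibble(term = terms, estimate = s$mean, std.error = s$sd,
                        conf.low = s$lower, conf.high = s$upper)
  if (!is.null(x$diagnostics)) {
    d <- x$diagnostics[match(pars, x$diagnostics$parameter), ]
    out$rhat <- d$rhat
    out$ess_bulk <- d$ess_bulk
  }
  out
}

#' One-row fit summary
#'
#' @param x An `occ_fit`.
#' @param ... Unused.
#' @return A one-row tibble: problem size, sampler size, worst convergence
#'   diagnostics.
#' @method glance occ_fit
#' @export
glance.occ_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = nrow(x$data),
    n_individuals = nrow(x$index),
    n_chains = x$sampler$chains,
    n_draws = nrow(x$draws),
    max_rhat = if (is.null(x$diagnostics)) NA_real_ else
      max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess_bulk = if (is.null(x$diagnostics)) NA_real_ else
      min(x$diagnostics$ess_bulk, na.rm = TRUE),
    n_flagged = length(x$flagged)
  )
}

#' Pooled logistic fit (no individual heterogeneity)
#'
#' Maximum-likelihood fit of the limiting model in which every individual
#' shares the same slopes (between-individual SDs forced to zero) and sex
#' and length act only through the intercept.  Used as a degenerate-case
#' check of the hierarchical likelihood; requires all sexes recorded.
#'
#' @param model_table Output of [assemble_model_table()].
#'
#' @return A list with `coefficients` (named: `alpha0`, `alpha1`, `alpha2`,
#'   `beta_cos`, `beta_sin`, `beta_logchl`, `beta_temperature`), `logLik`,
#'   and `convergence` (0 means the optimizer converged).
#' @export
fit_occurrence_pooled <- function(model_table) {
  idx <- occ_index(model_table)
  if (any(!idx$sex_known)) {
    rlang::abort("Pooled fit requires recorded sex for all individuals.")
  }
  ind <- match(model_table$tag_id, idx$tag_id)
  Z <- cbind(1, idx$male_indicator[ind], idx$length_centered[ind],
             as.matrix(model_table[, covariate_cols()]))
  y <- model_table$present
  nll <- function(th) {
    eta <- as.vector(Z %*% th)
    -(sum(y * eta) - sum(log1pexp(eta)))
  }
  gr <- function(th) {
    eta <- as.vector(Z %*% th)
    -as.vector(crossprod(Z, y - stats::plogis(eta)))
  }
  opt <- stats::optim(rep(0, ncol(Z)), nll, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  coefs <- stats::setNames(opt$par,
                           c("alpha0", "alpha1", "alpha2",
                             paste0("beta_", covariate_labels())))
  list(coefficients = coefs, logLik = -opt$value, convergence = opt$convergence)
}
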