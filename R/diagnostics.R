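#' Posterior-mean fitted occurrence probabilities
#'
#' For every row of the fitted model table, the posterior mean of
#' \eqn{p_{i,t}} averaged over all retained draws (individual intercepts
#' include the sampled latent sex for an unrecorded-sex individual).
#'
#' @param fit An `occ_fit`.
#'
#' @return The model table with a `fitted` column appended.
#' @export
fitted_probability <- function(fit) {
  out <- fit$data
  out$fitted <- NA_real_
  for (k in seq_len(nrow(fit$index))) {
    rows <- which(out$tag_id == fit$index$tag_id[k])
    X <- as.matrix(out[rows, covariate_cols()])
    B <- as.matrix(fit$draws[, paste0("beta[", k, ",", 1:4, "]")])
    b0 <- fit$draws[[paste0("beta0[", k, "]")]]
    eta <- X %*% t(B) + matrix(b0, nrow = length(rows), ncol = length(b0),
                               byrow = TRUE)
    out$fitted[rows] <- rowMeans(stats::plogis(eta))
  }
  out
}

# N x n_draw matrix of p_{i,t} for a subset of posterior draws
posterior_p_matrix <- function(fit, draw_idx) {
  P <- matrix(NA_real_, nrow = nrow(fit$data), ncol = length(draw_idx))
  for (k in seq_len(nrow(fit$index))) {
    rows <- which(fit$data$tag_id == fit$index$tag_id[k])
    B <- as.matrix(fit$draws[draw_idx, paste0("beta[", k, ",", 1:4, "]")])
    b0 <- fit$draws[[paste0("beta0[", k, "]")]][draw_idx]
    X <- as.matrix(fit$data[rows, covariate_cols()])
    P[rows, ] <- stats::plogis(X %*% t(B) +
                                 matrix(b0, nrow = length(rows),
                                        ncol = length(b0), byrow = TRUE))
  }
  P
}

bin_assignment <- function(fitted, n_bins) {
  n <- length(fitted)
  if (n_bins > n) rlang::abort("n_bins exceeds the number of observations.")
  ord <- order(fitted)                      # stable for ties
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) * n_bins / n)
  bin
}

#' Binned residuals for a binary-outcome fit
#'
#' Observations are sorted by fitted probability and split into `n_bins`
#' near-equal-count groups; within each bin the mean fitted probability and
#' the mean raw residual (observed minus fitted) are reported.  With a
#' well-calibrated model the mean residuals scatter around zero.
#'
#' @param data A data frame holding the observed 0/1 response and the
#'   pointwise fitted probabilities (e.g. [fitted_probability()] output).
#' @param n_bins Number of bins.  Default 100.
#' @param observed,fitted Names of the response and fitted columns.
#'
#' @return A tibble of class `"occ_binned"`: `bin`, `n`, `fitted_mean`,
#'   `resid_mean`.
#' @export
binned_residuals <- function(data, n_bins = 100, observed = "present",
                             fitted = "fitted") {
  y <- data[[observed]]
  p <- data[[fitted]]
  stopifnot(!is.null(y), !is.null(p), length(y) == length(p))
  bin <- bin_assignment(p, n_bins)
  out <- tibble::tibble(y = y, p = p, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     fitted_mean = mean(.data$p),
                     resid_mean = mean(.data$y - .data$p),
                     .groups = "drop")
  class(out) <- c("occ_binned", class(out))
  out
}

#' Posterior predictive envelope for binned residuals
#'
#' Simulates replicate presence series from the posterior predictive
#' distribution (one per sampled draw), bins each replicate's residuals with
#' the bin layout fixed by the posterior-mean fitted probabilities, and
#' returns per-bin central credible bounds together with the observed binned
#' residuals.  Observed bins falling outside the envelope flag days the
#' model does not capture.
#'
#' @param fit An `occ_fit`.
#' @param n_bins Number of bins.  Default 100.
#' @param n_rep Number of posterior predictive replicates.  Default 200.
#' @param level Envelope level.  Default 0.95.
#' @param seed Seed for the replicate simulation.
#'
#' @return A tibble of class `"occ_binned_envelope"`: `bin`, `n`,
#'   `fitted_mean`, `resid_mean` (observed), `lower`, `upper`, `inside`.
#' @export
residual_envelope <- function(fit, n_bins = 100, n_rep = 200, level = 0.95,
                              seed = 1) {
  stopifnot(n_rep >= 1)
  dat <- fitted_probability(fit)
  bin <- bin_assignment(dat$fitted, n_bins)
  obs <- binned_residuals(dat, n_bins = n_bins)
  rep_resid <- withr::with_seed(seed, {
    draw_idx <- sample.int(nrow(fit$draws), n_rep,
                           replace = n_rep > nrow(fit$draws))
    P <- posterior_p_matrix(fit, draw_idx)
    apply(P, 2, function(p) {
      yrep <- stats::rbinom(length(p), 1, p)
      as.numeric(rowsum(yrep - dat$fitted, bin) / tabulate(bin, n_bins))
    })
  })
  a <- (1 - level) / 2
  qs <- apply(rep_resid, 1, stats::quantile, probs = c(a, 1 - a))
  out <- obs
  out$lower <- qs[1, ]
  out$upper <- qs[2, ]
  out$inside <- out$resid_mean >= out$lower & out$resid_mean <= out$upper
  class(out) <- c("occ_binned_envelope", setdiff(class(out), "occ_binned_envelope"))
  out
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot binned residuals
#'
#' @param object An `"occ_binned"` or `"occ_binned_envelope"` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot occ_binned
#' @export
autoplot.occ_binned <- function(object, ...) {
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$fitted_mean,
                                             y = .data$resid_mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Mean fitted occurrence probability",
                  y = "Mean residual (observed - fitted)") +
    ggplot2::theme_minimal()
  if (all(c("lower", "upper") %in% names(object))) {
    gg <- gg +
      ggplot2::geom_line(ggplot2::aes(y = .data$lower), colour = "grey40") +
      ggplot2::geom_line(ggplot2::aes(y = .data$upper), colour = "grey40")
  }
  gg
}

#' @rdname autoplot.occ_binned
#' @method autoplot occ_binned_envelope
#' @export
autoplot.occ_binned_envelope <- autoplot.occ_binned
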