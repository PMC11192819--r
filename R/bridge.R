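# Bridge-sampling estimation of marginal likelihoods.
#
# The estimator is the iterative optimal bridge of Meng & Wong (1996) with a
# moment-matched multivariate-normal proposal on an unconstrained
# parameterisation (log for spreads, logit for the learning rate), using a
# split-half scheme: one half of the posterior draws fits the proposal, the
# other half enters the bridge identity, so the proposal is not tuned on the
# draws it is evaluated against.

#' Bridge-sampling estimate of a log marginal likelihood
#'
#' Generic estimator: given posterior draws on an unconstrained scale and a
#' function evaluating the log *unnormalised* posterior (log likelihood +
#' log prior + any transformation Jacobians) at a matrix of points, returns
#' the log normalising constant, i.e. the log marginal likelihood.
#'
#' The Monte-Carlo standard error follows the relative-mean-square-error
#' expression of Fruhwirth-Schnatter (2004), with a spectral-density estimate
#' of the variance of the posterior-side term to account for autocorrelation
#' in the MCMC draws.
#'
#' @param draws Matrix of posterior draws (rows = draws, columns =
#'   unconstrained parameters).
#' @param log_posterior Function taking such a matrix and returning the log
#'   unnormalised posterior for each row.
#' @param nprop Number of proposal draws; defaults to the number of
#'   bridge-side posterior draws.
#' @param seed Seed for the proposal draws.
#' @param tol Convergence tolerance on successive log-estimates.
#' @param max_iter Iteration cap; non-convergence is an error, never ignored.
#' @return A list with `logml`, `mc_se`, and `niter`.
#' @export
bridge_lml <- function(draws, log_posterior, nprop = NULL, seed = 1,
                       tol = 1e-10, max_iter = 1000) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 20) stop("too few posterior draws for bridge sampling", call. = FALSE)
  fit_half <- draws[seq_len(n %/% 2), , drop = FALSE]
  use_half <- draws[(n %/% 2 + 1):n, , drop = FALSE]

  m <- colMeans(fit_half)
  S <- stats::cov(fit_half)
  diag(S) <- diag(S) + 1e-10 * (1 + abs(diag(S)))
  ch <- chol(S)

  n1 <- nrow(use_half)
  n2 <- as.integer(nprop %||% n1)
  prop <- withr::with_seed(seed, rmvnorm_chol(n2, m, ch))

  # log ratio q_post / q_prop at posterior draws (l1) and proposal draws (l2)
  l1 <- log_posterior(use_half) - dmvnorm_chol_log(use_half, m, ch)
  l2 <- log_posterior(prop) - dmvnorm_chol_log(prop, m, ch)
  if (any(!is.finite(l1))) {
    stop("non-finite log posterior at retained posterior draws", call. = FALSE)
  }
  keep <- is.finite(l2)
  l2 <- l2[keep] # proposal points of zero posterior support contribute zero
  n2_eff <- n2
  s1 <- n1 / (n1 + n2_eff)
  s2 <- n2_eff / (n1 + n2_eff)

  lstar <- median(l1)
  r <- 1
  for (it in seq_len(max_iter)) {
    num <- exp(l2 - lstar) / (s1 * exp(l2 - lstar) + s2 * r)
    den <- 1 / (s1 * exp(l1 - lstar) + s2 * r)
    r_new <- (sum(num) / n2_eff) / (sum(den) / n1)
    if (!is.finite(r_new) || r_new <= 0) {
      stop("bridge iteration diverged", call. = FALSE)
    }
    done <- abs(log(r_new) - log(r)) < tol
    r <- r_new
    if (done) break
    if (it == max_iter) stop("bridge iteration failed to converge", call. = FALSE)
  }
  logml <- log(r) + lstar

  f1 <- exp(l2 - lstar) / (s1 * exp(l2 - lstar) + s2 * r)
  f2 <- 1 / (s1 * exp(l1 - lstar) + s2 * r)
  var_f2 <- tryCatch(coda::spectrum0.ar(f2)$spec, error = function(e) var(f2))
  re2 <- var(f1) / (n2_eff * mean(f1)^2) + var_f2 / (n1 * mean(f2)^2)
  list(logml = logml, mc_se = sqrt(re2), niter = it)
}

#' Importance-sampling estimate of a log marginal likelihood
#'
#' Simple normal-proposal importance sampler over the same unconstrained
#' parameterisation; provided as an independent cross-check of the bridge
#' estimator on low-dimensional models.
#'
#' @inheritParams bridge_lml
#' @param mean,cov Proposal mean vector and covariance matrix.
#' @param n Number of importance draws.
#' @return A list with `logml` and `mc_se`.
#' @export
importance_lml <- function(log_posterior, mean, cov, n = 10000, seed = 1) {
  cov <- as.matrix(cov)
  diag(cov) <- diag(cov) + 1e-12
  ch <- chol(cov)
  x <- withr::with_seed(seed, rmvnorm_chol(n, mean, ch))
  lw <- log_posterior(x) - dmvnorm_chol_log(x, mean, ch)
  lw <- lw[is.finite(lw)]
  logml <- log_mean_exp(lw)
  w <- exp(lw - max(lw))
  mc_se <- sd(w) / (mean(w) * sqrt(length(w)))
  list(logml = logml, mc_se = mc_se)
}

# ---- unconstrained parameterisation of a releval_fit ------------------------

# Columns: b0, slopes, u[1..J], log(tau), log(sigma), [qlogis(alpha)]
transform_draws <- function(fit) {
  d <- fit$draws
  ucols <- grep("^u\\[", colnames(d), value = TRUE)
  slopes <- model_slopes(fit$model_id)
  out <- cbind(
    d[, c("b0", slopes, ucols), drop = FALSE],
    log_tau = log(d[, "tau"]),
    log_sigma = log(d[, "sigma"])
  )
  if (fit$model_id == "td") out <- cbind(out, logit_alpha = qlogis(d[, "alpha"]))
  out
}

# Log unnormalised posterior on the unconstrained scale, vectorised over rows.
make_log_posterior <- function(fit) {
  dat <- fit$data
  pri <- fit$priors
  y <- dat$y
  pid <- dat$pid
  N <- dat$N
  J <- dat$J
  K <- dat$K
  model_id <- fit$model_id
  X <- dat$X
  xs <- dat$xs

  function(theta) {
    theta <- as.matrix(theta)
    b0 <- theta[, 1]
    beta <- theta[, 1 + seq_len(K), drop = FALSE]
    u <- theta[, 1 + K + seq_len(J), drop = FALSE]
    log_tau <- theta[, 2 + K + J]
    log_sigma <- theta[, 3 + K + J]
    tau <- exp(log_tau)
    sigma <- exp(log_sigma)

    if (model_id == "td") {
      alpha <- plogis(theta[, 4 + K + J])
      pred <- vapply(seq_len(nrow(theta)), function(m) {
        v <- xs[, 1]
        a <- alpha[m]
        for (t in 2:7) v <- v + a * (xs[, t] - v)
        v * beta[m, 1]
      }, numeric(N))
    } else {
      pred <- X %*% t(beta)
    }
    mu <- sweep(pred, 2, b0, "+") + t(u)[pid, , drop = FALSE]
    sse <- colSums((y - mu)^2)
    loglik <- -N * log(sigma) - N / 2 * log(2 * pi) - sse / (2 * sigma^2)

    lp <- loglik +
      dnorm(b0, pri$intercept_mean, pri$intercept_sd, log = TRUE) +
      rowSums(dnorm(beta, pri$slope_mean, pri$slope_sd, log = TRUE)) +
      rowSums(dnorm(u, 0, tau, log = TRUE)) +
      dhalf_t_log(tau, pri$group_sd_df, pri$group_sd_scale) + log_tau +
      dhalf_t_log(sigma, pri$resid_sd_df, pri$resid_sd_scale) + log_sigma
    if (model_id == "td") {
      a <- plogis(theta[, 4 + K + J])
      lp <- lp + log(a) + log1p(-a) # U(0,1) density is 1; logit Jacobian
    }
    lp
  }
}

#' Log marginal likelihood of a fitted evaluation model
#'
#' Bridge-sampling estimate of the model's log marginal likelihood — the
#' probability of the observed bids with all parameters (including the
#' participant intercepts) integrated out against their priors. Ratios of
#' marginal likelihoods between models fitted to identical data are Bayes
#' factors.
#'
#' @param fit A `releval_fit` (or `releval_mixture`).
#' @param nprop,seed,tol,max_iter Passed to [bridge_lml()].
#' @return A list with `logml`, `mc_se` (Monte-Carlo error), and `niter`.
#' @export
log_marginal_likelihood <- function(fit, nprop = NULL, seed = 1,
                                    tol = 1e-10, max_iter = 1000) {
  UseMethod("log_marginal_likelihood")
}

#' @export
log_marginal_likelihood.releval_fit <- function(fit, nprop = NULL, seed = 1,
                                                tol = 1e-10, max_iter = 1000) {
  bridge_lml(transform_draws(fit), make_log_posterior(fit),
             nprop = nprop, seed = seed, tol = tol, max_iter = max_iter)
}

#' Bayes factor between two fitted models
#'
#' `exp(lml_a - lml_b)`: the relative evidence for model A over model B.
#' Both fits must be on identical response data, otherwise the comparison is
#' meaningless and an error is signalled.
#'
#' @param fit_a,fit_b `releval_fit` objects on the same bids.
#' @param lml_a,lml_b Optional precomputed [log_marginal_likelihood()]
#'   results (recomputed if absent).
#' @param seed Seed for any marginal-likelihood estimation.
#' @return A list with `bf` (Bayes factor for A over B), `log_bf`, and a
#'   Wagenmakers-style verbal `label`.
#' @export
bayes_factor <- function(fit_a, fit_b, lml_a = NULL, lml_b = NULL, seed = 1) {
  if (!isTRUE(all.equal(fit_a$data$y, fit_b$data$y))) {
    stop("fits are not on identical response data", call. = FALSE)
  }
  lml_a <- lml_a %||% log_marginal_likelihood(fit_a, seed = seed)
  lml_b <- lml_b %||% log_marginal_likelihood(fit_b, seed = seed)
  log_bf <- lml_a$logml - lml_b$logml
  list(bf = exp(log_bf), log_bf = log_bf, label = bf_label(exp(log_bf)))
}

#' Verbal evidence label for a Bayes factor
#'
#' The conventional evidence categories (anecdotal, moderate, strong, very
#' strong, extreme) for the first model over the second; Bayes factors below
#' 1 are labelled as evidence for the second model.
#'
#' @param bf A Bayes factor (> 0).
#' @return A character label.
#' @export
bf_label <- function(bf) {
  stopifnot(bf > 0)
  direction <- if (bf >= 1) "for" else "against"
  b <- max(bf, 1 / bf)
  grade <- if (b == 1) "no evidence"
  else if (b < 3) "anecdotal evidence"
  else if (b < 10) "moderate evidence"
  else if (b < 30) "strong evidence"
  else if (b < 100) "very strong evidence"
  else "extreme evidence"
  if (b == 1) grade else paste(grade, direction, "the first model")
}

#' Rank fitted models by marginal likelihood
#'
#' Orders a set of fits (on identical response data) by their estimated log
#' marginal likelihood, best first, and reports the Bayes factor of the best
#' model over each other model — the format in which model comparisons are
#' usually tabulated. Fits whose `max_rhat` exceeds 1.05 are refused unless
#' `force = TRUE`.
#'
#' @param fits A named or unnamed list of `releval_fit` objects.
#' @param lmls Optional list of precomputed [log_marginal_likelihood()]
#'   results, parallel to `fits`.
#' @param seed Seed for marginal-likelihood estimation.
#' @param force Compare despite non-converged fits.
#' @return A tibble with columns `model_id`, `logml`, `mc_se`, `max_rhat`,
#'   `bf_best_vs_this` (1 for the winner) and `label`, ordered best first.
#' @export
select_best <- function(fits, lmls = NULL, seed = 1, force = FALSE) {
  stopifnot(length(fits) >= 1)
  y0 <- fits[[1]]$data$y
  for (f in fits[-1]) {
    if (!isTRUE(all.equal(y0, f$data$y))) {
      stop("all fits must be on identical response data", call. = FALSE)
    }
  }
  rhats <- vapply(fits, function(f) f$max_rhat, numeric(1))
  if (!force && any(rhats > 1.05)) {
    stop(sprintf(
      "fit(s) %s have max R-hat > 1.05; rerun longer or use force = TRUE",
      paste(vapply(fits[rhats > 1.05], function(f) f$model_id, ""),
            collapse = ", ")), call. = FALSE)
  }
  if (is.null(lmls)) {
    lmls <- lapply(fits, log_marginal_likelihood, seed = seed)
  }
  logml <- vapply(lmls, function(l) l$logml, numeric(1))
  ord <- order(logml, decreasing = TRUE)
  log_bf <- logml[ord[1]] - logml[ord]
  tibble::tibble(
    model_id = vapply(fits, function(f) f$model_id, "")[ord],
    logml = logml[ord],
    mc_se = vapply(lmls, function(l) l$mc_se, numeric(1))[ord],
    max_rhat = rhats[ord],
    bf_best_vs_this = exp(log_bf),
    label = vapply(exp(pmax(log_bf, 0)), bf_label, "")
  )
}
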