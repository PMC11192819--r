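# Trial-level strategy mixture: each trial is generated by the recalled-items,
# presented-items, or both regression, with per-participant mixing weights.

mixture_model_string <- "model {
  for (i in 1:N) {
    base[i] <- a[pid[i]]
    l1[i] <- log(theta[pid[i], 1]) +
      logdensity.norm(y[i], base[i] + beta_recall * xr[i], prec_y)
    l2[i] <- log(theta[pid[i], 2]) +
      logdensity.norm(y[i], base[i] + beta_presented * xp[i], prec_y)
    l3[i] <- log(theta[pid[i], 3]) +
      logdensity.norm(y[i], base[i] + beta_recall_both * xr[i] + beta_presented_both * xp[i], prec_y)
    mmax[i] <- max(max(l1[i], l2[i]), l3[i])
    ll[i] <- mmax[i] + log(exp(l1[i] - mmax[i]) + exp(l2[i] - mmax[i]) +
                           exp(l3[i] - mmax[i]))
    zeros[i] ~ dpois(C - ll[i])
  }
  # intercepts sampled on the centred scale for Gibbs mixing; converted to
  # deviations u_j = a_j - b0 after sampling
  for (j in 1:J) {
    a[j] ~ dnorm(b0, prec_u)
    theta[j, 1:3] ~ ddirch(dir_prior[])
  }
  beta_recall ~ dnorm(slope_mean, pow(slope_sd, -2))
  beta_presented ~ dnorm(slope_mean, pow(slope_sd, -2))
  beta_recall_both ~ dnorm(slope_mean, pow(slope_sd, -2))
  beta_presented_both ~ dnorm(slope_mean, pow(slope_sd, -2))
  b0 ~ dnorm(intercept_mean, pow(intercept_sd, -2))
  tau ~ dt(0, pow(group_sd_scale, -2), group_sd_df) T(0,)
  sigma ~ dt(0, pow(resid_sd_scale, -2), resid_sd_df) T(0,)
  prec_u <- pow(tau, -2)
  prec_y <- pow(sigma, -2)
}"

#' Fit the trial-level strategy mixture model
#'
#' Each trial's bid is assumed generated by one of three component
#' regressions — recalled-items only, presented-items only, or both — with
#' per-participant component probabilities `theta_j` on the 3-simplex under a
#' flat Dirichlet(1, 1, 1) prior. The component indicators are marginalised
#' analytically inside the likelihood (a theta-weighted mixture of normal
#' densities), which leaves the posterior unchanged while letting the Gibbs
#' sampler move freely.
#'
#' Each component has its own population-level slope(s) — `beta_recall` for
#' the recalled component, `beta_presented` for the presented component, and
#' `beta_recall_both` / `beta_presented_both` for the both component — shared
#' across participants within the component; participant heterogeneity enters
#' only through the intercepts `u_j` and the weights `theta_j`. The intercept
#' structure and the residual spread are shared across components, so
#' components cannot explain variance through differing noise levels.
#' Because the components are nested regressions on highly correlated
#' predictors, a population in which nobody uses a component leaves that
#' component's slopes prior-driven and able to mimic a neighbouring
#' component; weight recovery is therefore assessed on mixed populations
#' (see the package vignette).
#'
#' @param design A design table from [build_design()] (both predictors
#'   present on every row).
#' @param priors A [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @return A `releval_mixture`: posterior draws (including every `theta[j,k]`),
#'   posterior-mean per-participant weights `theta_mean` (rows on the
#'   simplex), per-trial posterior component probabilities `z` (rows sum to
#'   1), the data block, and `max_rhat`.
#' @export
fit_mixture <- function(design, priors = prior_config(), mcmc = mcmc_config()) {
  if (anyNA(design$predictor_recalled)) {
    stop("mixture design requires the recalled predictor on every trial",
         call. = FALSE)
  }
  participants <- sort(unique(design$participant_id))
  pid <- match(design$participant_id, participants)
  N <- nrow(design)
  J <- length(participants)
  jd <- list(
    y = design$bid, xr = design$predictor_recalled,
    xp = design$predictor_presented, pid = pid, N = N, J = J,
    zeros = rep(0L, N), C = 1000, dir_prior = c(1, 1, 1),
    slope_mean = priors$slope_mean, slope_sd = priors$slope_sd,
    intercept_mean = priors$intercept_mean, intercept_sd = priors$intercept_sd,
    group_sd_df = priors$group_sd_df, group_sd_scale = priors$group_sd_scale,
    resid_sd_df = priors$resid_sd_df, resid_sd_scale = priors$resid_sd_scale
  )
  # start every chain at the same plausible point (slopes at the prior mean,
  # equal weights, intercepts from participant means): mixture posteriors can
  # have minor secondary modes that trap a chain started from a dispersed
  # draw, and R-hat would then flag a mode split rather than slow mixing
  ybar_j <- tapply(design$bid, pid, mean)
  inits <- list(
    beta_recall = priors$slope_mean, beta_presented = priors$slope_mean,
    beta_recall_both = priors$slope_mean / 2,
    beta_presented_both = priors$slope_mean / 2,
    b0 = mean(design$bid) - priors$slope_mean * mean(design$predictor_presented),
    a = as.numeric(ybar_j - priors$slope_mean * mean(design$predictor_presented)),
    theta = matrix(1 / 3, J, 3), sigma = sd(design$bid) / 2, tau = 1
  )
  samples <- run_jags(mixture_model_string, jd,
                      c("b0", "beta_recall", "beta_presented",
                        "beta_recall_both", "beta_presented_both",
                        "tau", "sigma", "a", "theta"), mcmc,
                      extra_inits = inits)
  draws <- as.matrix(samples)
  acols <- grep("^a\\[", colnames(draws))
  draws[, acols] <- draws[, acols] - draws[, "b0"]
  colnames(draws)[acols] <- sub("^a\\[", "u[", colnames(draws)[acols])

  theta_mean <- matrix(NA_real_, J, 3,
                       dimnames = list(participants,
                                       c("recalled", "presented", "both")))
  for (k in 1:3) {
    theta_mean[, k] <- colMeans(draws[, sprintf("theta[%d,%d]", 1:J, k),
                                      drop = FALSE])
  }

  fit <- structure(
    list(
      draws = draws,
      chain = rep(seq_along(samples), each = nrow(samples[[1]])),
      theta_mean = theta_mean,
      z = mixture_trial_probs(draws, jd),
      data = c(jd[c("y", "xr", "xp", "pid", "N", "J")],
               list(participants = participants)),
      priors = priors,
      mcmc = mcmc,
      max_rhat = max_rhat(samples)
    ),
    class = "releval_mixture"
  )
  fit
}

# Per-trial posterior component probabilities, averaged over posterior draws:
# z_ik proportional to theta_jk * Normal(y_i | mu_ik, sigma) at each draw.
mixture_trial_probs <- function(draws, jd) {
  M <- nrow(draws)
  use <- seq(1, M, by = max(1L, M %/% 500L)) # thin for speed; z is a summary
  z <- matrix(0, jd$N, 3)
  for (m in use) {
    b0 <- draws[m, "b0"]
    br <- draws[m, "beta_recall"]
    bp <- draws[m, "beta_presented"]
    brb <- draws[m, "beta_recall_both"]
    bpb <- draws[m, "beta_presented_both"]
    sigma <- draws[m, "sigma"]
    u <- draws[m, sprintf("u[%d]", seq_len(jd$J))]
    th <- cbind(draws[m, sprintf("theta[%d,1]", jd$pid)],
                draws[m, sprintf("theta[%d,2]", jd$pid)],
                draws[m, sprintf("theta[%d,3]", jd$pid)])
    base <- b0 + u[jd$pid]
    lk <- cbind(
      dnorm(jd$y, base + br * jd$xr, sigma, log = TRUE),
      dnorm(jd$y, base + bp * jd$xp, sigma, log = TRUE),
      dnorm(jd$y, base + brb * jd$xr + bpb * jd$xp, sigma, log = TRUE)
    ) + log(th)
    lk <- exp(lk - apply(lk, 1, max))
    z <- z + lk / rowSums(lk)
  }
  z <- z / length(use)
  dimnames(z) <- list(NULL, c("recalled", "presented", "both"))
  z
}

#' @export
print.releval_mixture <- function(x, ...) {
  cat(sprintf("<releval_mixture> %d trials, %d participants, max R-hat %.4f\n",
              x$data$N, x$data$J, x$max_rhat))
  print(classify_participants(x)$counts)
  invisible(x)
}

#' Classify participants by dominant strategy
#'
#' Assigns each participant the component with the largest posterior-mean
#' mixture weight; exact ties go to `"both"` (the conservative choice, since
#' "both" nests the other components' predictors).
#'
#' @param fit A `releval_mixture`.
#' @return A list with `assignments` (tibble: `participant_id`, the three
#'   posterior-mean weights, `strategy`) and `counts` (named integer vector
#'   over recalled / presented / both).
#' @export
classify_participants <- function(fit) {
  th <- fit$theta_mean
  strategy <- apply(th, 1, function(p) {
    top <- which(p == max(p))
    if (length(top) > 1) "both" else colnames(th)[top]
  })
  assignments <- tibble::tibble(
    participant_id = fit$data$participants,
    theta_recalled = th[, "recalled"],
    theta_presented = th[, "presented"],
    theta_both = th[, "both"],
    strategy = unname(strategy)
  )
  counts <- vapply(c("recalled", "presented", "both"),
                   function(s) sum(strategy == s), integer(1))
  list(assignments = assignments, counts = counts)
}

#' Write the per-participant mixture summary
#'
#' One CSV row per participant: posterior-mean weights and the strategy
#' classification.
#'
#' @param fit A `releval_mixture`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mixture_csv <- function(fit, path) {
  readr::write_csv(classify_participants(fit)$assignments, path)
  invisible(path)
}

# ---- marginal likelihood of the mixture (sanity bridge to single models) ----

# Unconstrained scale: b0, beta_recall, beta_presented, u[1..J], log tau,
# log sigma, then per participant the additive log-ratio transform of theta.
#' @export
log_marginal_likelihood.releval_mixture <- function(fit, nprop = NULL, seed = 1,
                                                    tol = 1e-10, max_iter = 1000) {
  J <- fit$data$J
  d <- fit$draws
  th <- array(NA_real_, c(nrow(d), J, 3))
  for (k in 1:3) th[, , k] <- d[, sprintf("theta[%d,%d]", 1:J, k)]
  alr1 <- log(th[, , 1] / th[, , 3])
  alr2 <- log(th[, , 2] / th[, , 3])
  colnames(alr1) <- sprintf("alr1[%d]", 1:J)
  colnames(alr2) <- sprintf("alr2[%d]", 1:J)
  draws <- cbind(
    d[, c("b0", "beta_recall", "beta_presented", "beta_recall_both",
          "beta_presented_both", sprintf("u[%d]", 1:J)), drop = FALSE],
    log_tau = log(d[, "tau"]), log_sigma = log(d[, "sigma"]), alr1, alr2
  )
  bridge_lml(draws, make_mixture_log_posterior(fit),
             nprop = nprop, seed = seed, tol = tol, max_iter = max_iter)
}

make_mixture_log_posterior <- function(fit) {
  dat <- fit$data
  pri <- fit$priors
  J <- dat$J

  function(theta_mat) {
    theta_mat <- as.matrix(theta_mat)
    M <- nrow(theta_mat)
    b0 <- theta_mat[, 1]
    br <- theta_mat[, 2]
    bp <- theta_mat[, 3]
    brb <- theta_mat[, 4]
    bpb <- theta_mat[, 5]
    u <- theta_mat[, 5 + seq_len(J), drop = FALSE]
    log_tau <- theta_mat[, 6 + J]
    log_sigma <- theta_mat[, 7 + J]
    a1 <- theta_mat[, 7 + J + seq_len(J), drop = FALSE]
    a2 <- theta_mat[, 7 + 2 * J + seq_len(J), drop = FALSE]
    tau <- exp(log_tau)
    sigma <- exp(log_sigma)

    vapply(seq_len(M), function(m) {
      denom <- 1 + exp(a1[m, ]) + exp(a2[m, ])
      th <- cbind(exp(a1[m, ]), exp(a2[m, ]), 1) / denom
      base <- b0[m] + u[m, dat$pid]
      lk <- cbind(
        dnorm(dat$y, base + br[m] * dat$xr, sigma[m], log = TRUE) +
          log(th[dat$pid, 1]),
        dnorm(dat$y, base + bp[m] * dat$xp, sigma[m], log = TRUE) +
          log(th[dat$pid, 2]),
        dnorm(dat$y, base + brb[m] * dat$xr + bpb[m] * dat$xp, sigma[m],
              log = TRUE) + log(th[dat$pid, 3])
      )
      mx <- apply(lk, 1, max)
      loglik <- sum(mx + log(rowSums(exp(lk - mx))))
      # Dirichlet(1,1,1) has density 2 on the simplex; ALR Jacobian is
      # prod(theta); u prior depends on tau.
      loglik +
        dnorm(b0[m], pri$intercept_mean, pri$intercept_sd, log = TRUE) +
        dnorm(br[m], pri$slope_mean, pri$slope_sd, log = TRUE) +
        dnorm(bp[m], pri$slope_mean, pri$slope_sd, log = TRUE) +
        dnorm(brb[m], pri$slope_mean, pri$slope_sd, log = TRUE) +
        dnorm(bpb[m], pri$slope_mean, pri$slope_sd, log = TRUE) +
        sum(dnorm(u[m, ], 0, tau[m], log = TRUE)) +
        dhalf_t_log(tau[m], pri$group_sd_df, pri$group_sd_scale) + log_tau[m] +
        dhalf_t_log(sigma[m], pri$resid_sd_df, pri$resid_sd_scale) + log_sigma[m] +
        sum(log(2) + rowSums(log(th)))
    }, numeric(1))
  }
}
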