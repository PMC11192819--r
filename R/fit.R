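#' Prior configuration for the hierarchical evaluation models
#'
#' Weakly informative priors for the willingness-to-pay regressions: each
#' slope gets a Normal(1, 0.5) prior (centred on the incentive-compatible
#' slope of 1), the population intercept a Normal(0, 10), the
#' between-participant intercept spread a half-Student-t(3, 0, 10), and the
#' temporal-difference learning rate a Uniform(0, 1). The residual spread is
#' given the same half-Student-t(3, 0, 10) as the group spread — a fixed
#' prior, chosen for reproducibility over the data-dependent default some
#' regression front-ends use. All scales are in Galactic Credits.
#'
#' @param slope_mean,slope_sd Normal prior on each regression slope.
#' @param intercept_mean,intercept_sd Normal prior on the population intercept.
#' @param group_sd_df,group_sd_scale Half-Student-t prior on the participant
#'   intercept spread tau.
#' @param resid_sd_df,resid_sd_scale Half-Student-t prior on the residual
#'   spread sigma.
#' @return A list of class `releval_priors`.
#' @export
prior_config <- function(slope_mean = 1, slope_sd = 0.5,
                         intercept_mean = 0, intercept_sd = 10,
                         group_sd_df = 3, group_sd_scale = 10,
                         resid_sd_df = 3, resid_sd_scale = 10) {
  stopifnot(slope_sd > 0, intercept_sd > 0, group_sd_scale > 0,
            resid_sd_scale > 0)
  structure(
    list(slope_mean = slope_mean, slope_sd = slope_sd,
         intercept_mean = intercept_mean, intercept_sd = intercept_sd,
         group_sd_df = group_sd_df, group_sd_scale = group_sd_scale,
         resid_sd_df = resid_sd_df, resid_sd_scale = resid_sd_scale),
    class = "releval_priors"
  )
}

#' MCMC sampler configuration
#'
#' Defaults match the reference analysis settings: 1000 warmup iterations
#' plus 4000 retained iterations on each of four chains; the
#' temporal-difference model, whose learning rate mixes more slowly, uses
#' 5000 warmup plus 10000 retained iterations ([mcmc_config_td()]). Reduced
#' desk-scale settings for simulation studies are available via
#' [recovery_preset()].
#'
#' @param warmup Warmup (adaptation + burn-in) iterations per chain.
#' @param samples Retained iterations per chain.
#' @param chains Number of chains (>= 2, so that R-hat is defined).
#' @param seed Integer seed; chain c uses `seed + c`.
#' @return A list of class `releval_mcmc`.
#' @export
mcmc_config <- function(warmup = 1000, samples = 4000, chains = 4, seed = 1) {
  if (chains < 2) stop("at least 2 chains are required", call. = FALSE)
  structure(
    list(warmup = as.integer(warmup), samples = as.integer(samples),
         chains = as.integer(chains), seed = as.integer(seed)),
    class = "releval_mcmc"
  )
}

#' @rdname mcmc_config
#' @export
mcmc_config_td <- function(warmup = 5000, samples = 10000, chains = 4, seed = 1) {
  mcmc_config(warmup = warmup, samples = samples, chains = chains, seed = seed)
}

# ---- internal JAGS machinery -------------------------------------------------

# Sampling parameterisation: participant intercepts are hierarchically
# centred (a_j ~ N(b0c, tau)) and predictors are mean-centred inside the
# sampler, with the conditional prior on the shifted intercept b0c given the
# slopes set to N(intercept_mean + beta.xbar, intercept_sd) so the joint
# prior is exactly the stated one. Both are pure reparameterisations that
# leave the posterior unchanged but mix far better under Gibbs sampling;
# draws are converted back to (b0, u_j) afterwards.
jags_model_string <- function(model_id) {
  likelihood <- if (model_id == "td") {
    "  for (i in 1:N) {
    V[i, 1] <- xs[i, 1]
    for (t in 2:7) { V[i, t] <- V[i, t - 1] + alpha * (xs[i, t] - V[i, t - 1]) }
    mu[i] <- a[pid[i]] + beta[1] * (V[i, 7] - xbar[1])
    y[i] ~ dnorm(mu[i], prec_y)
  }
  alpha ~ dunif(0, 1)"
  } else {
    "  for (i in 1:N) {
    mu[i] <- a[pid[i]] + inprod(beta[], Xc[i, ])
    y[i] ~ dnorm(mu[i], prec_y)
  }"
  }
  paste0("model {\n", likelihood, "
  for (j in 1:J) { a[j] ~ dnorm(b0c, prec_u) }
  for (k in 1:K) { beta[k] ~ dnorm(slope_mean, pow(slope_sd, -2)) }
  b0c ~ dnorm(intercept_mean + inprod(beta[], xbar[]), pow(intercept_sd, -2))
  tau ~ dt(0, pow(group_sd_scale, -2), group_sd_df) T(0,)
  sigma ~ dt(0, pow(resid_sd_scale, -2), resid_sd_df) T(0,)
  prec_u <- pow(tau, -2)
  prec_y <- pow(sigma, -2)
}\n")
}

model_slopes <- function(model_id) {
  switch(model_id,
    recalled = "beta_recall",
    presented = "beta_presented",
    both = c("beta_recall", "beta_presented"),
    td = "beta_td"
  )
}

# Shared data block: response, participant index, predictors, prior constants.
fit_data <- function(design, model_id, priors) {
  participants <- sort(unique(design$participant_id))
  pid <- match(design$participant_id, participants)
  dat <- list(
    y = design$bid, pid = pid, N = nrow(design), J = length(participants),
    K = length(model_slopes(model_id)),
    slope_mean = priors$slope_mean, slope_sd = priors$slope_sd,
    intercept_mean = priors$intercept_mean, intercept_sd = priors$intercept_sd,
    group_sd_df = priors$group_sd_df, group_sd_scale = priors$group_sd_scale,
    resid_sd_df = priors$resid_sd_df, resid_sd_scale = priors$resid_sd_scale
  )
  if (model_id == "td") {
    dat$xs <- as.matrix(design[, paste0("v", 1:7)])
    dat$xbar <- mean(dat$xs)
  } else {
    X <- switch(model_id,
      recalled = cbind(design$predictor_recalled),
      presented = cbind(design$predictor_presented),
      both = cbind(design$predictor_recalled, design$predictor_presented)
    )
    dat$X <- X
    dat$xbar <- colMeans(X)
  }
  dat$participants <- participants
  dat
}

# jags-side data: centred design and centring constants
jags_data <- function(dat, model_id) {
  jd <- dat[setdiff(names(dat), c("participants", "X"))]
  if (model_id != "td") {
    jd$Xc <- sweep(dat$X, 2, dat$xbar)
  }
  jd$xbar <- as.vector(dat$xbar)
  jd
}

run_jags <- function(model_string, data, monitor, mcmc, extra_inits = NULL) {
  inits <- lapply(seq_len(mcmc$chains), function(c) {
    c(list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = mcmc$seed + c),
      extra_inits)
  })
  adapt <- max(100L, mcmc$warmup %/% 2L)
  burn <- mcmc$warmup - adapt
  # JAGS warns when its samplers would still like to adapt; at the chain
  # lengths used for simulation studies this is routine and the convergence
  # check below (R-hat) is the arbiter, so the warning is muffled.
  model <- withCallingHandlers(
    rjags::jags.model(
      textConnection(model_string), data = data, inits = inits,
      n.chains = mcmc$chains, n.adapt = adapt, quiet = TRUE
    ),
    warning = function(w) {
      if (grepl("Adaptation incomplete", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (burn > 0) update(model, burn, progress.bar = "none")
  rjags::coda.samples(model, monitor, n.iter = mcmc$samples,
                      progress.bar = "none")
}

max_rhat <- function(coda_samples) {
  gd <- coda::gelman.diag(coda_samples, autoburnin = FALSE,
                          multivariate = FALSE)
  max(gd$psrf[, 1], na.rm = TRUE)
}

# ---- fit construction --------------------------------------------------------

new_fit <- function(model_id, coda_samples, data, priors, mcmc) {
  draws <- as.matrix(coda_samples)
  chain <- rep(seq_along(coda_samples), each = nrow(coda_samples[[1]]))
  slopes <- model_slopes(model_id)
  cn <- colnames(draws)
  cn[cn == "beta"] <- slopes[1]
  for (k in seq_along(slopes)) cn[cn == sprintf("beta[%d]", k)] <- slopes[k]
  colnames(draws) <- cn
  # undo the sampling reparameterisation: b0 = b0c - beta.xbar, u = a - b0c
  b0c <- draws[, "b0c"]
  acols <- grep("^a\\[", cn)
  draws[, acols] <- draws[, acols] - b0c
  colnames(draws)[acols] <- sub("^a\\[", "u[", cn[acols])
  b0 <- b0c - as.vector(draws[, slopes, drop = FALSE] %*% data$xbar)
  draws[, "b0c"] <- b0
  colnames(draws)[colnames(draws) == "b0c"] <- "b0"
  structure(
    list(
      model_id = model_id,
      draws = draws,
      chain = chain,
      data = data,
      priors = priors,
      mcmc = mcmc,
      max_rhat = max_rhat(coda_samples)
    ),
    class = "releval_fit"
  )
}

#' @export
print.releval_fit <- function(x, ...) {
  cat(sprintf("<releval_fit> model '%s': %d draws (%d chains), %d trials, %d participants\n",
              x$model_id, nrow(x$draws), x$mcmc$chains, x$data$N, x$data$J))
  cat(sprintf("  max R-hat: %.4f%s\n", x$max_rhat,
              if (x$max_rhat > 1.05) "  [NOT CONVERGED]" else ""))
  print(fit_summary(x), n = 8)
  invisible(x)
}

#' Posterior summary of a fit
#'
#' @param fit A `releval_fit`.
#' @return A tibble with posterior mean, sd and central 95% interval for the
#'   population-level parameters (participant intercepts omitted).
#' @export
fit_summary <- function(fit) {
  keep <- !grepl("^u\\[", colnames(fit$draws))
  d <- fit$draws[, keep, drop = FALSE]
  tibble::tibble(
    parameter = colnames(d),
    mean = colMeans(d),
    sd = apply(d, 2, sd),
    q2.5 = apply(d, 2, quantile, 0.025),
    q97.5 = apply(d, 2, quantile, 0.975)
  )
}

#' Fit a hierarchical evaluation-model regression
#'
#' Fits, by Gibbs sampling in JAGS, the Bayesian multilevel regression of
#' bids on the chosen model's trial-level predictor(s):
#' `bid_ij ~ Normal(b0 + u_j + sum_k beta_k x_ijk, sigma)` with participant
#' intercepts `u_j ~ Normal(0, tau)` and the priors in [prior_config()].
#' Convergence is summarised by the largest split-chain potential scale
#' reduction factor (`max_rhat`); fits with `max_rhat` above 1.05 are flagged
#' and refused by [select_best()] unless forced. Non-convergence is reported
#' in the returned object, never silently dropped.
#'
#' @param design A design table from [build_design()].
#' @param model_id `"recalled"`, `"presented"`, or `"both"`.
#' @param priors A [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @return A `releval_fit`: posterior draws (population intercept, slopes,
#'   participant intercepts, tau, sigma), the data block, and `max_rhat`.
#' @export
fit_hierarchical <- function(design, model_id = c("recalled", "presented", "both"),
                             priors = prior_config(), mcmc = mcmc_config()) {
  model_id <- match.arg(model_id)
  if (model_id %in% c("recalled", "both") && anyNA(design$predictor_recalled)) {
    stop("design contains missing recalled predictors; use build_design()",
         call. = FALSE)
  }
  dat <- fit_data(design, model_id, priors)
  samples <- run_jags(jags_model_string(model_id), jags_data(dat, model_id),
                      c("b0c", "beta", "tau", "sigma", "a"), mcmc)
  new_fit(model_id, samples, dat, priors, mcmc)
}

#' Fit the temporal-difference evaluation model
#'
#' As [fit_hierarchical()], but the trial-level predictor is the
#' temporal-difference value of the raw sequence, recomputed inside the
#' sampler at the current learning rate, so the posterior is joint over
#' `(alpha, b0, u_j, beta, tau, sigma)`. The learning rate has a
#' Uniform(0, 1) prior.
#'
#' @param design A design table from [build_design()] (the raw stimulus
#'   columns `v1`..`v7` are required).
#' @param priors A [prior_config()].
#' @param mcmc An [mcmc_config()]; [mcmc_config_td()] gives the longer
#'   default run this model uses.
#' @return A `releval_fit` with `model_id = "td"`.
#' @export
fit_td <- function(design, priors = prior_config(), mcmc = mcmc_config_td()) {
  dat <- fit_data(design, "td", priors)
  samples <- run_jags(jags_model_string("td"), jags_data(dat, "td"),
                      c("alpha", "b0c", "beta", "tau", "sigma", "a"), mcmc)
  new_fit("td", samples, dat, priors, mcmc)
}

#' Serialize a fit to JSON
#'
#' Writes the model id, prior and sampler settings, posterior summaries,
#' `max_rhat`, and (if supplied) the log marginal likelihood with its
#' Monte-Carlo error.
#'
#' @param fit A `releval_fit`.
#' @param path Output path.
#' @param lml Optional result of [log_marginal_likelihood()].
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, lml = NULL) {
  out <- list(
    model_id = fit$model_id,
    priors = unclass(fit$priors),
    mcmc = unclass(fit$mcmc),
    n_trials = fit$data$N,
    n_participants = fit$data$J,
    max_rhat = fit$max_rhat,
    posterior_summary = fit_summary(fit)
  )
  if (!is.null(lml)) {
    out$log_marginal_likelihood <- lml$logml
    out$log_marginal_likelihood_mc_se <- lml$mc_se
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
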