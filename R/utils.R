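# Internal numerical helpers shared across the fitting and bridge-sampling code.

#' @importFrom stats rnorm dnorm runif rpois dt var median sd qlogis plogis
#'   integrate quantile setNames complete.cases cov update
#' @importFrom rlang .data
NULL

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_mean_exp <- function(x) logsumexp(x) - log(length(x))

# Multivariate normal log density via a pre-computed Cholesky factor of the
# covariance. `x` is a matrix with one row per point.
dmvnorm_chol_log <- function(x, mean, chol_cov) {
  x <- as.matrix(x)
  p <- ncol(x)
  z <- backsolve(chol_cov, t(x) - mean, transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(chol_cov))) - 0.5 * colSums(z^2)
}

rmvnorm_chol <- function(n, mean, chol_cov) {
  p <- length(mean)
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% chol_cov, 2, mean, "+")
}

# half-Student-t log density (location 0) on x > 0
dhalf_t_log <- function(x, df, scale) {
  ifelse(x < 0, -Inf, log(2) + dt(x / scale, df = df, log = TRUE) - log(scale))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}
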