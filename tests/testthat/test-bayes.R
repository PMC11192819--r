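# The bridge-sampling estimator, the hierarchical fits, and the JZS Bayes
# factor, each checked against an independent oracle.

test_that("bridge sampler reproduces the analytic conjugate marginal likelihood", {
  # y_i ~ N(mu, s^2) with s known, mu ~ N(m0, t0^2): the marginal likelihood
  # is multivariate normal with covariance s^2 I + t0^2 J (analytic oracle)
  set.seed(31)
  n <- 25; s <- 2; m0 <- 1; t0 <- 3
  y <- rnorm(n, 1.7, s)
  Sig <- diag(s^2, n) + t0^2
  lml_true <- as.numeric(
    -0.5 * determinant(Sig)$modulus - 0.5 * crossprod(y - m0, solve(Sig, y - m0)) -
      n / 2 * log(2 * pi))

  vpost <- 1 / (n / s^2 + 1 / t0^2)
  mpost <- vpost * (sum(y) / s^2 + m0 / t0^2)
  logpost <- function(th) {
    vapply(as.matrix(th)[, 1], function(mu) {
      sum(dnorm(y, mu, s, log = TRUE)) + dnorm(mu, m0, t0, log = TRUE)
    }, numeric(1))
  }
  draws <- matrix(rnorm(4000, mpost, sqrt(vpost)), ncol = 1)
  bridge <- bridge_lml(draws, logpost, seed = 5)
  expect_lt(abs(bridge$logml - lml_true), 0.1)

  # the importance-sampling fallback agrees on the same conjugate model
  imp <- importance_lml(logpost, mpost, matrix(vpost * 4), n = 20000, seed = 6)
  expect_lt(abs(imp$logml - lml_true), 0.1)

  # two bridge runs with different proposal seeds agree within Monte-Carlo error
  bridge2 <- bridge_lml(draws, logpost, seed = 99)
  expect_lt(abs(bridge$logml - bridge2$logml),
            3 * max(bridge$mc_se, bridge2$mc_se) + 1e-3)
})

test_that("hierarchical regression recovers known generating parameters", {
  d <- generate_dataset(33, gen_params("presented", beta_presented = 1, sigma = 2),
                        spc_params(), seed = 32)
  f <- fit_hierarchical(build_design(d), "presented", mcmc = quick_mcmc(1))
  expect_lte(f$max_rhat, 1.05)
  expect_equal(nrow(f$draws), 2 * 500) # chains x samples
  sm <- fit_summary(f)
  beta <- sm[sm$parameter == "beta_presented", ]
  expect_true(beta$q2.5 <= 1 && 1 <= beta$q97.5)
  sig <- sm[sm$parameter == "sigma", ]
  expect_lt(abs(sig$mean - 2), 0.3)
})

test_that("a zero group spread concentrates the tau posterior near zero", {
  d <- generate_dataset(20, gen_params("presented", tau = 0, sigma = 2),
                        spc_params(), seed = 33)
  f <- fit_hierarchical(build_design(d), "presented", mcmc = quick_mcmc(2))
  expect_lt(median(f$draws[, "tau"]), 2 / 4) # sigma / 4
})

test_that("TD fit recovers the learning rate and stays in its support", {
  d <- generate_dataset(10, gen_params("td", alpha = 0.7), spc_params(),
                        seed = 34)
  f <- fit_td(build_design(d), mcmc = quick_mcmc(3))
  a <- f$draws[, "alpha"]
  expect_true(all(a > 0 & a < 1))
  expect_lt(abs(mean(a) - 0.7), 0.1)

  # under presented-mean data a small learning rate mimics the flat average,
  # so the posterior shifts toward low alpha rather than staying near 0.7
  dp <- generate_dataset(10, gen_params("presented"), spc_params(), seed = 35)
  fp <- fit_td(build_design(dp), mcmc = quick_mcmc(4))
  expect_lt(mean(fp$draws[, "alpha"]), 0.5)

  # with no signal at all the learning rate stays prior-diffuse
  dn <- generate_dataset(10, gen_params("presented", sigma = 60), spc_params(),
                         seed = 36)
  fn <- fit_td(build_design(dn), mcmc = quick_mcmc(5))
  expect_gt(sd(fn$draws[, "alpha"]), 5 * sd(a))
})

test_that("marginal-likelihood comparison favours the generating model", {
  d <- generate_dataset(8, gen_params("presented"), spc_params(), seed = 36)
  des <- build_design(d)
  fp <- fit_hierarchical(des, "presented",
                         mcmc = quick_mcmc(5, warmup = 800, samples = 800))
  fr <- fit_hierarchical(des, "recalled",
                         mcmc = quick_mcmc(6, warmup = 800, samples = 800))
  lp <- log_marginal_likelihood(fp)
  lr <- log_marginal_likelihood(fr)
  expect_gt(lp$logml, lr$logml)

  bf <- bayes_factor(fp, fr, lml_a = lp, lml_b = lr)
  expect_gt(bf$bf, 1)
  # reciprocity and self-identity
  bf_rev <- bayes_factor(fr, fp, lml_a = lr, lml_b = lp)
  expect_equal(bf$bf * bf_rev$bf, 1, tolerance = 1e-10)
  expect_equal(bayes_factor(fp, fp, lml_a = lp, lml_b = lp)$bf, 1)

  ranking <- select_best(list(fp, fr), lmls = list(lp, lr))
  expect_equal(ranking$model_id[1], "presented")

  # mismatched response data is an invalid comparison
  d2 <- generate_dataset(8, gen_params("presented"), spc_params(), seed = 37)
  f2 <- fit_hierarchical(build_design(d2), "presented", mcmc = quick_mcmc(7))
  expect_error(bayes_factor(fp, f2), "identical response data")
})

test_that("select_best orders by marginal likelihood and reports Bayes factors", {
  fake_fit <- function(id) {
    structure(list(model_id = id, data = list(y = 1:5), max_rhat = 1.0),
              class = "releval_fit")
  }
  fits <- list(fake_fit("recalled"), fake_fit("presented"), fake_fit("td"))
  lmls <- list(list(logml = -100, mc_se = 0.1), list(logml = -110, mc_se = 0.1),
               list(logml = -105, mc_se = 0.1))
  r <- select_best(fits, lmls = lmls)
  expect_equal(r$model_id, c("recalled", "td", "presented"))
  expect_equal(r$bf_best_vs_this, c(1, exp(5), exp(10)))

  single <- select_best(fits[1], lmls = lmls[1])
  expect_equal(nrow(single), 1)
  expect_equal(single$bf_best_vs_this, 1)

  # non-converged fits are refused unless forced
  bad <- fake_fit("presented"); bad$max_rhat <- 1.2
  expect_error(select_best(list(fits[[1]], bad), lmls = lmls[1:2]), "R-hat")
  forced <- select_best(list(fits[[1]], bad), lmls = lmls[1:2], force = TRUE)
  expect_equal(nrow(forced), 2)
})

test_that("JZS Bayes factor matches a Monte-Carlo integration oracle", {
  # null-favouring limit and monotonicity
  for (n in c(10, 30, 80)) expect_lt(jzs_bf_from_t(0, n, n - 1), 1)
  ts <- seq(0, 6, by = 0.5)
  bfs <- vapply(ts, function(t) jzs_bf_from_t(t, 30, 29), numeric(1))
  expect_true(all(diff(bfs) > 0))

  # Monte-Carlo oracle: sample g from its inverse-gamma mixture and average
  set.seed(38)
  r <- sqrt(2) / 2
  for (i in 1:20) {
    t <- runif(1, 0, 5)
    n <- sample(5:100, 1)
    df <- n - 1
    g <- 1 / rgamma(2e6, shape = 0.5, rate = r^2 / 2)
    num <- mean((1 + n * g)^(-0.5) *
                  (1 + t^2 / ((1 + n * g) * df))^(-(df + 1) / 2))
    bf_mc <- num / (1 + t^2 / df)^(-(df + 1) / 2)
    expect_lt(abs(jzs_bf_from_t(t, n, df) / bf_mc - 1), 0.01)
  }

  # interface checks
  set.seed(39)
  x <- rnorm(20, 1); y <- rnorm(20)
  expect_equal(jzs_ttest_bf(x, y, paired = TRUE)$bf10,
               jzs_ttest_bf(x - y)$bf10)
  two <- jzs_ttest_bf(x, y)
  expect_equal(two$df, 38)
  expect_gt(two$bf10, 0)
  expect_error(jzs_ttest_bf(rep(1, 5)), "zero-variance")
})
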