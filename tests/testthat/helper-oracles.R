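# Independent oracles and shared fixtures for the test suite.

# Closed-form exponential-weights expansion of the temporal-difference value:
# w_1 = (1 - a)^(T-1), w_t = a (1 - a)^(T-t) for t >= 2. Kept independent of
# the package's recursive implementation.
td_weights_oracle <- function(alpha, T = 7) {
  w <- c((1 - alpha)^(T - 1),
         vapply(2:T, function(t) alpha * (1 - alpha)^(T - t), numeric(1)))
  w
}

td_value_oracle <- function(values, alpha) {
  sum(td_weights_oracle(alpha, length(values)) * values)
}

# Short MCMC settings for simulation tests.
quick_mcmc <- function(seed = 1, warmup = 400, samples = 500) {
  mcmc_config(warmup = warmup, samples = samples, chains = 2, seed = seed)
}

# A mixed-strategy population: n_per participants generated from each of the
# three mixture components, with the matching generator slopes.
gen_mixed_population <- function(n_per, seed) {
  sets <- list(recalled = gen_params("recalled"),
               presented = gen_params("presented"),
               both = gen_params("both"))
  out <- vector("list", length(sets))
  truth <- character(0)
  for (k in seq_along(sets)) {
    d <- generate_dataset(n_per, sets[[k]], spc_params(), seed = seed + k)
    d$participant_id <- d$participant_id + (k - 1) * n_per
    out[[k]] <- d
    truth <- c(truth, rep(names(sets)[k], n_per))
  }
  list(data = dplyr::bind_rows(out), truth = truth)
}

# Memoised mixed-population mixture fit, shared between the mixture unit
# tests and the acceptance suite (the fit takes ~1 min).
.fixtures <- new.env()

mixture_fixture <- function() {
  if (is.null(.fixtures$mixture)) {
    mp <- gen_mixed_population(4, seed = 300)
    des <- build_design(mp$data)
    fit <- fit_mixture(des, mcmc = mcmc_config(warmup = 1500, samples = 1200,
                                               chains = 2, seed = 7))
    .fixtures$mixture <- list(pop = mp, design = des, fit = fit)
  }
  .fixtures$mixture
}

# A small toy trial table exercising every exclusion rule. Participants:
#   1: complete, accurate                      -> included, all complete
#   2: only 24/32 trials complete (75%)       -> incomplete_trials
#   3: recalls mostly wrong (<1 correct/trial) -> low_recall
#   4: only 24/32 bids present (75%)           -> incomplete_eval
#   5: one bid of 150                          -> flagged bid_out_of_range
toy_exclusion_table <- function() {
  base_row <- function(pid, t, recalls, bid) {
    tibble::tibble(
      participant_id = pid, trial_index = t,
      task_order = if (t %% 2 == 0) "RE" else "ER",
      v1 = 50L, v2 = 51L, v3 = 52L, v4 = 53L, v5 = 54L, v6 = 55L, v7 = 56L,
      recalls = recalls, bid = bid, selling_price = 55, earnings = 100
    )
  }
  rows <- list()
  for (t in 1:32) {
    rows[[length(rows) + 1]] <- base_row(1, t, "50;51;52", 53)
    rows[[length(rows) + 1]] <- base_row(2, t,
      if (t <= 24) "50;51" else NA_character_, if (t <= 24) 53 else NA_real_)
    rows[[length(rows) + 1]] <- base_row(3, t, "10;11", 53)
    rows[[length(rows) + 1]] <- base_row(4, t, "50;51",
      if (t <= 24) 53 else NA_real_)
    rows[[length(rows) + 1]] <- base_row(5, t, "50;51", if (t == 1) 150 else 53)
  }
  dplyr::bind_rows(rows)
}
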