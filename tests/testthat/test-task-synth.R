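test_that("sequence generator respects the stated structure and bounds", {
  set.seed(11)
  means <- integer(300)
  for (i in 1:300) {
    s <- generate_sequence()
    expect_length(s$values, 7)
    expect_identical(s$dist_hi - s$dist_lo, 58L)
    expect_identical(s$dist_lo, s$dist_mean - 29L)
    expect_identical(s$dist_hi, s$dist_mean + 29L)
    expect_true(all(s$values >= s$dist_lo & s$values <= s$dist_hi))
    expect_true(all(s$values >= 11 & s$values <= 99))
    expect_equal(s$true_value, mean(s$values))
    means[i] <- s$dist_mean
  }
  expect_true(all(means >= 40 & means <= 70))
})

test_that("pooled stimulus offsets are uniform over the generating range", {
  set.seed(12)
  offsets <- unlist(lapply(1:10000, function(i) {
    s <- generate_sequence()
    s$values - s$dist_mean
  }))
  counts <- table(factor(offsets, levels = -29:29))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("recall simulator matches its per-position probabilities", {
  s <- structure(list(values = c(45L, 50L, 55L, 60L, 65L, 70L, 75L),
                      dist_mean = 60L, dist_lo = 31L, dist_hi = 89L,
                      true_value = 60),
                 class = "releval_sequence")
  certain <- spc_params(p_recall = rep(1, 7), intrusion_rate = 0)
  set.seed(13)
  expect_setequal(simulate_recall(s, certain, "RE"), s$values)
  none <- spc_params(p_recall = rep(0, 7), intrusion_rate = 0)
  expect_length(simulate_recall(s, none, "RE"), 0)

  p <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  sp <- spc_params(p_recall = p, intrusion_rate = 0, max_outputs = 7)
  set.seed(14)
  hits <- matrix(0, 10000, 7)
  for (i in 1:10000) {
    r <- simulate_recall(s, sp, "RE")
    hits[i, ] <- s$values %in% r
  }
  expect_true(all(abs(colMeans(hits) - p) < 0.02))

  # ER order attenuates the last two positions only
  sp_er <- spc_params(p_recall = p, recency_attenuation_er = 0.5,
                      intrusion_rate = 0, max_outputs = 7)
  set.seed(15)
  hits_er <- matrix(0, 10000, 7)
  for (i in 1:10000) {
    r <- simulate_recall(s, sp_er, "ER")
    hits_er[i, ] <- s$values %in% r
  }
  expect_true(all(abs(colMeans(hits_er) - p * c(rep(1, 5), 0.5, 0.5)) < 0.02))

  expect_error(spc_params(p_recall = rep(1.2, 7)), "0, 1")
})

test_that("bid generators invert the evaluation models", {
  s <- structure(list(values = c(20L, 30L, 40L, 50L, 60L, 70L, 80L),
                      dist_mean = 50L, dist_lo = 21L, dist_hi = 79L,
                      true_value = 50),
                 class = "releval_sequence")
  noiseless <- gen_params("presented", b0 = 0, beta_presented = 1, sigma = 1e-12)
  expect_equal(simulate_bid(s, integer(0), noiseless), 50)
  rec <- gen_params("recalled", b0 = 0, beta_recall = 1, sigma = 1e-12)
  expect_equal(simulate_bid(s, c(50L, 60L), rec), 55)
  expect_error(simulate_bid(s, integer(0), rec), "non-empty recall")
  expect_error(simulate_bid(s, integer(0), gen_params("both", sigma = 1)),
               "non-empty recall")

  # noisy bids are centred on the linear predictor
  gp <- gen_params("presented", b0 = 2, beta_presented = 0.9, sigma = 4)
  set.seed(16)
  bids <- replicate(5000, simulate_bid(s, integer(0), gp, participant_intercept = 1))
  expect_lt(abs(mean(bids) - (2 + 1 + 0.9 * 50)), 4 / sqrt(5000) * 4)
})

test_that("BDM payoff follows the auction rule and is incentive compatible", {
  expect_equal(bdm_payoff(30, 55, 60), 100)
  expect_equal(bdm_payoff(70, 55, 60), 105)
  expect_equal(bdm_payoff(55, 55, 60), 100 - 55 + 60) # tie resolves as purchase
  expect_error(bdm_payoff(150, 55, 60), "required range")

  # exhaustive grid: expected earnings over the price distribution peak at
  # bid == true value
  prices <- seq(40, 70, by = 0.005)
  for (tv in c(41.5, 55, 68.2)) {
    bids <- seq(0, 100, by = 0.25)
    expected <- vapply(bids, function(b) mean(bdm_payoff(b, prices, tv)),
                       numeric(1))
    best_bid <- bids[which.max(expected)]
    expect_lt(abs(best_bid - tv), 0.26)
    # truthful bidding beats every bid further than one grid step away
    off <- abs(bids - tv) > 0.3
    expect_true(all(mean(bdm_payoff(tv, prices, tv)) >= expected[off]))
  }
})

test_that("generated datasets are balanced, complete, and seed-deterministic", {
  d <- generate_dataset(6, gen_params("recalled"), spc_params(), seed = 17)
  expect_equal(nrow(d), 6 * 32)
  counts <- dplyr::count(d, participant_id, task_order)
  expect_true(all(counts$n == 16))
  expect_true(all(nchar(d$recalls) > 0)) # recalled generator needs recalls
  expect_true(all(d$bid >= 0 & d$bid <= 100))
  expect_true(all(d$selling_price >= 40 & d$selling_price <= 70))
  expect_equal(d$earnings,
               bdm_payoff(d$bid, d$selling_price,
                          rowMeans(d[, paste0("v", 1:7)])))

  d2 <- generate_dataset(6, gen_params("recalled"), spc_params(), seed = 17)
  expect_identical(d, d2)
  d3 <- generate_dataset(6, gen_params("recalled"), spc_params(), seed = 18)
  expect_false(identical(d, d3))
})

test_that("trial tables survive a CSV and JSON round trip", {
  d <- generate_dataset(3, gen_params("presented"), spc_params(), seed = 19)
  d$bid[5] <- NA # a missing evaluation response
  d$recalls[8] <- NA # an unattempted recall
  d$recalls[9] <- "" # attempted, nothing reported
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(d, csv)
  back <- read_trial_table(csv)
  expect_equal(as.data.frame(back), as.data.frame(d))

  js <- withr::local_tempfile(fileext = ".json")
  write_trial_table(d, js, format = "json")
  back_js <- read_trial_table(js, format = "json")
  expect_equal(back_js$recalls, d$recalls)
  expect_equal(back_js$bid, d$bid)
})
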