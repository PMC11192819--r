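test_that("recall scoring is greedy, exact-match, and conserves reports", {
  vals <- c(50L, 61L, 72L, 50L, 83L, 94L, 15L)
  perfect <- score_recall(vals, sample(vals))
  expect_true(all(perfect$correct))
  expect_equal(perfect$intrusions, 0L)

  # duplicated presented value: a single report credits the earliest position
  one <- score_recall(vals, 50L)
  expect_equal(which(one$correct), 1L)
  # a second token of the same value credits the later position
  two <- score_recall(vals, c(50L, 50L))
  expect_equal(which(two$correct), c(1L, 4L))
  # a third token has no position left: it is an intrusion
  three <- score_recall(vals, c(50L, 50L, 50L))
  expect_equal(three$intrusions, 1L)

  never <- score_recall(vals, 42L)
  expect_equal(sum(never$correct), 0L)
  expect_equal(never$intrusions, 1L)

  set.seed(51)
  for (i in 1:50) {
    reports <- sample(11:99, sample(0:8, 1), replace = TRUE)
    sc <- score_recall(vals, reports)
    expect_equal(sum(sc$correct) + sc$intrusions, length(reports))
    expect_lte(sum(sc$correct), 7)
  }
})

test_that("exclusion filters implement the pre-registered rules", {
  toy <- toy_exclusion_table()
  ex <- apply_exclusions(toy)
  reasons <- setNames(ex$report$excluded$reasons,
                      ex$report$excluded$participant_id)
  expect_setequal(ex$report$excluded$participant_id, c(2, 3, 4))
  expect_match(reasons[["2"]], "incomplete_trials")
  expect_equal(reasons[["3"]], "low_recall")
  expect_equal(reasons[["4"]], "incomplete_eval")
  expect_equal(ex$eval_excluded_ids, 5)
  expect_equal(ex$report$n_included, 2)
  expect_setequal(unique(ex$clean$participant_id), c(1, 5))
  expect_equal(ex$report$n_complete_all_trials, 2)

  # a participant at exactly 78% completion (25/32) is excluded
  p25 <- dplyr::filter(toy, participant_id == 1) |>
    dplyr::mutate(participant_id = 9,
                  recalls = dplyr::if_else(trial_index > 25, NA_character_, recalls),
                  bid = dplyr::if_else(trial_index > 25, NA_real_, bid))
  ex2 <- apply_exclusions(dplyr::bind_rows(toy, p25))
  expect_match(ex2$report$excluded$reasons[
    ex2$report$excluded$participant_id == 9], "incomplete_trials")

  # averaging 0.8 correct items per trial is below the one-item rule
  p08 <- dplyr::filter(toy, participant_id == 1) |>
    dplyr::mutate(participant_id = 10,
                  recalls = dplyr::if_else(trial_index %% 5 == 0, "10", "50"))
  ex3 <- apply_exclusions(dplyr::bind_rows(toy, p08))
  expect_match(ex3$report$excluded$reasons[
    ex3$report$excluded$participant_id == 10], "low_recall")

  expect_error(apply_exclusions(dplyr::select(toy, -bid)), "missing columns")

  json <- withr::local_tempfile(fileext = ".json")
  write_exclusion_json(ex$report, json)
  expect_true(jsonlite::validate(paste(readLines(json), collapse = "")))
})

test_that("complete-trials subset keeps only fully observed participants", {
  toy <- toy_exclusion_table()
  sub <- complete_trials_subset(toy)
  expect_setequal(unique(sub$participant_id), c(1, 3, 5))
})

test_that("serial position curve means and Morey SEM match hand computation", {
  # two participants with known per-position accuracy, identical -> SEM 0
  mk <- function(pid, recalls) {
    tibble::tibble(
      participant_id = pid, trial_index = 1:2, task_order = "RE",
      v1 = 50L, v2 = 51L, v3 = 52L, v4 = 53L, v5 = 54L, v6 = 55L, v7 = 56L,
      recalls = recalls, bid = 50, selling_price = 55, earnings = 100
    )
  }
  same <- dplyr::bind_rows(mk(1, c("50;51", "50")), mk(2, c("50;51", "50")))
  curve <- spc(same)
  expect_equal(curve$mean_correct, c(1, 0.5, 0, 0, 0, 0, 0))
  expect_equal(curve$sem, rep(0, 7))

  diff <- dplyr::bind_rows(mk(1, c("50;51;52", "50;51;52")), mk(2, c("50", "50")))
  curve2 <- spc(diff)
  expect_equal(curve2$mean_correct, c(1, 0.5, 0.5, 0, 0, 0, 0))
  # hand-computed Morey SEM: centred scores differ by +-(1 - 3/7) at
  # positions 2 and 3 ... reproduce numerically
  P <- rbind(c(1, 1, 1, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0, 0))
  centred <- P - rowMeans(P) + mean(P)
  sem_hand <- apply(centred, 2, sd) / sqrt(2) * sqrt(7 / 6)
  expect_equal(curve2$sem, sem_hand)

  expect_error(spc(mk(1, c("50", "50"))), "fewer than 2")
})

test_that("synthetic serial position curves track the generating profile", {
  sp <- spc_params()
  d <- generate_dataset(40, gen_params("presented"), sp, seed = 52)
  curve <- spc(d)
  re <- dplyr::filter(curve, task_order == "RE")
  er <- dplyr::filter(curve, task_order == "ER")
  # value-based greedy scoring shifts credit for duplicated values toward
  # earlier positions, so allow a wider band than raw Monte-Carlo error
  expect_true(all(abs(re$mean_correct - sp$p_recall) < 0.08))
  expected_er <- sp$p_recall * c(rep(1, 5), rep(sp$recency_attenuation_er, 2))
  expect_true(all(abs(er$mean_correct - expected_er) < 0.08))
  # qualitative structure: primacy, recency, and reduced recency under delay
  expect_gt(re$mean_correct[1], re$mean_correct[3])
  expect_gt(re$mean_correct[7], re$mean_correct[5])
  expect_true(all(er$mean_correct[6:7] < re$mean_correct[6:7]))
  expect_true(all(abs(er$mean_correct[1:5] - re$mean_correct[1:5]) < 0.06))
})

test_that("willingness-to-pay RMSE matches brute-force computation", {
  mk <- function(bids) {
    tibble::tibble(
      participant_id = 1, trial_index = seq_along(bids), task_order = "RE",
      v1 = 48L, v2 = 49L, v3 = 50L, v4 = 50L, v5 = 50L, v6 = 51L, v7 = 52L,
      recalls = "50", bid = bids, selling_price = 55, earnings = 100
    )
  }
  expect_equal(wtp_rmse(mk(rep(50, 4)))$rmse, 0)
  expect_equal(wtp_rmse(mk(60))$rmse, 10)
  bids <- c(45, 57, 61)
  expect_equal(wtp_rmse(mk(bids))$rmse, sqrt(mean((bids - 50)^2)))

  d <- generate_dataset(6, gen_params("presented"), spc_params(), seed = 53)
  by_ord <- wtp_rmse(d, by_order = TRUE)
  expect_equal(nrow(by_ord), 12)
  expect_true(all(by_ord$rmse >= 0))
})

test_that("task-order contrasts return defined Bayes factors", {
  d <- generate_dataset(12, gen_params("presented"), spc_params(), seed = 54)
  tc <- task_order_contrasts(d)
  expect_equal(tc$measure, c("recall_accuracy", "wtp_rmse"))
  expect_true(all(is.finite(tc$bf10)))
  expect_true(all(tc$n == 12))
  # the generator attenuates ER recall, so RE accuracy should be higher
  expect_gt(tc$mean_RE[1], tc$mean_ER[1])
})
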