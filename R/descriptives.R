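# Pre-registered exclusion filters and behavioural summaries.

#' Score one trial's recall
#'
#' Greedy value-based scoring: each report, in output order, is matched to
#' the earliest presented position holding that value that has not yet been
#' matched. Matched positions are correct; reports that match nothing
#' (values never presented, or duplicates beyond the available tokens) are
#' intrusions. Correctness is exact integer match.
#'
#' @param values The 7 presented values in presentation order.
#' @param reports Integer vector of reported values in output order.
#' @return A list with `correct` (logical vector over the 7 positions) and
#'   `intrusions` (count). `sum(correct) + intrusions == length(reports)`.
#' @export
score_recall <- function(values, reports) {
  correct <- rep(FALSE, 7)
  intrusions <- 0L
  for (r in reports) {
    pos <- which(values == r & !correct)
    if (length(pos) > 0) {
      correct[pos[1]] <- TRUE
    } else {
      intrusions <- intrusions + 1L
    }
  }
  list(correct = correct, intrusions = intrusions)
}

# Per-trial correctness matrix for attempted recall trials.
recall_scores <- function(dataset) {
  vals <- as.matrix(dataset[, paste0("v", 1:7)])
  rec <- parse_recalls(dataset$recalls)
  attempted <- !vapply(rec, is.null, logical(1))
  correct <- matrix(NA, nrow(dataset), 7)
  intr <- rep(NA_integer_, nrow(dataset))
  for (i in which(attempted)) {
    sc <- score_recall(vals[i, ], rec[[i]])
    correct[i, ] <- sc$correct
    intr[i] <- sc$intrusions
  }
  list(attempted = attempted, correct = correct, intrusions = intr)
}

#' Apply the pre-registered exclusion filters
#'
#' Participants are excluded when they (a) completed fewer than 80% of the
#' 32 trials (a trial counts as completed when at least one of its two
#' responses is present; the stricter per-task rules below handle one-sided
#' gaps), (b) averaged fewer than one correctly recalled
#' item per attempted recall trial, or (c) completed fewer than 80% of the
#' evaluation trials. Participants with any bid outside the required 0-100
#' range are additionally flagged for exclusion from evaluation analyses
#' (they remain in the recall analyses). The filters are applied to the full
#' table, so the resulting inclusion set does not depend on the order in
#' which the rules are stated.
#'
#' @param dataset A long-format trial table (see [generate_dataset()] /
#'   [read_trial_table()]).
#' @param n_trials Nominal number of trials per participant.
#' @return A list with `clean` (the table restricted to included
#'   participants), `eval_excluded_ids` (bid-range flags), and `report`, a
#'   list holding `excluded` (tibble of `participant_id` and semicolon-joined
#'   `reasons` from \{incomplete_trials, low_recall, incomplete_eval\}),
#'   `flagged_bid_out_of_range`, `n_included`, and `n_complete_all_trials`
#'   (participants with every trial complete — the subset used for the joint
#'   model comparison).
#' @export
apply_exclusions <- function(dataset, n_trials = 32L) {
  required <- c("participant_id", "trial_index", "task_order",
                paste0("v", 1:7), "recalls", "bid")
  missing_cols <- setdiff(required, names(dataset))
  if (length(missing_cols) > 0) {
    stop("malformed trial table; missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(dataset$participant_id) | is.na(dataset$trial_index))
  if (length(bad) > 0) {
    stop("malformed rows (missing participant or trial index): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }

  sc <- recall_scores(dataset)
  per <- dataset |>
    dplyr::mutate(
      recall_attempted = sc$attempted,
      n_correct = rowSums(sc$correct),
      eval_done = !is.na(.data$bid),
      trial_complete = sc$attempted | !is.na(.data$bid),
      bid_bad = !is.na(.data$bid) & (.data$bid < 0 | .data$bid > 100)
    ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      prop_complete = sum(.data$trial_complete) / n_trials,
      mean_correct = mean(.data$n_correct[.data$recall_attempted]),
      prop_eval = sum(.data$eval_done) / n_trials,
      any_bad_bid = any(.data$bid_bad),
      all_complete = sum(.data$recall_attempted & .data$eval_done) == n_trials
    )

  reasons <- lapply(seq_len(nrow(per)), function(i) {
    r <- character(0)
    if (per$prop_complete[i] < 0.8) r <- c(r, "incomplete_trials")
    if (!is.nan(per$mean_correct[i]) && per$mean_correct[i] < 1) {
      r <- c(r, "low_recall")
    }
    if (per$prop_eval[i] < 0.8) r <- c(r, "incomplete_eval")
    r
  })
  excluded_idx <- which(lengths(reasons) > 0)
  excluded <- tibble::tibble(
    participant_id = per$participant_id[excluded_idx],
    reasons = vapply(reasons[excluded_idx], paste, "", collapse = ";")
  )
  flagged <- per$participant_id[per$any_bad_bid]
  included <- setdiff(per$participant_id, excluded$participant_id)
  clean <- dplyr::filter(dataset, .data$participant_id %in% included)

  list(
    clean = clean,
    eval_excluded_ids = flagged,
    report = list(
      excluded = excluded,
      flagged_bid_out_of_range = flagged,
      n_total = nrow(per),
      n_included = length(included),
      n_complete_all_trials = sum(per$all_complete &
                                    per$participant_id %in% included)
    )
  )
}

#' Restrict to participants who completed every trial
#'
#' The joint model comparison (which includes the temporal-difference model)
#' requires complete data, so only participants with both responses on all
#' `n_trials` trials are kept.
#'
#' @inheritParams apply_exclusions
#' @return The restricted trial table.
#' @export
complete_trials_subset <- function(dataset, n_trials = 32L) {
  rec <- parse_recalls(dataset$recalls)
  ok <- dataset |>
    dplyr::mutate(complete = !vapply(rec, is.null, logical(1)) &
                    !is.na(.data$bid)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(all_done = sum(.data$complete) == n_trials)
  keep <- ok$participant_id[ok$all_done]
  dplyr::filter(dataset, .data$participant_id %in% keep)
}

#' Write an exclusion report as JSON
#'
#' @param report The `report` element from [apply_exclusions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Serial position curve with within-subject error bars
#'
#' Mean proportion of items recalled at each serial position, split by task
#' order, with within-subject standard errors computed by the
#' Cousineau-Morey method: each participant's position scores are shifted by
#' (grand mean - participant mean) before the between-participant SE is
#' taken, and the result is inflated by sqrt(K / (K - 1)) with K = 7
#' positions.
#'
#' @param dataset A long-format trial table.
#' @return A tibble with `task_order`, `position`, `mean_correct`, `sem`,
#'   and `n_participants`.
#' @export
spc <- function(dataset) {
  sc <- recall_scores(dataset)
  K <- 7
  out <- list()
  for (ord in sort(unique(dataset$task_order))) {
    idx <- which(dataset$task_order == ord & sc$attempted)
    if (length(idx) == 0) next
    pid <- dataset$participant_id[idx]
    sums <- rowsum(sc$correct[idx, , drop = FALSE] + 0, pid)
    props <- sums / as.vector(table(pid)[rownames(sums)])
    if (nrow(props) < 2) {
      stop("within-subject SEM undefined with fewer than 2 participants",
           call. = FALSE)
    }
    centred <- props - rowMeans(props) + mean(props)
    sem <- apply(centred, 2, sd) / sqrt(nrow(props)) * sqrt(K / (K - 1))
    out[[ord]] <- tibble::tibble(
      task_order = ord, position = 1:7,
      mean_correct = colMeans(props), sem = sem,
      n_participants = nrow(props)
    )
  }
  dplyr::bind_rows(out)
}

#' Willingness-to-pay accuracy (RMSE)
#'
#' Per-participant root mean square error between bids and the sequences'
#' true values (the mean of the presented values), optionally split by task
#' order.
#'
#' @param dataset A long-format trial table.
#' @param by_order Split by task order.
#' @return A tibble with `participant_id`, (`task_order`,) `rmse`, `n_trials`.
#' @export
wtp_rmse <- function(dataset, by_order = FALSE) {
  dat <- dataset |>
    dplyr::mutate(true_value = rowMeans(dataset[, paste0("v", 1:7)])) |>
    dplyr::filter(!is.na(.data$bid))
  grp <- if (by_order) c("participant_id", "task_order") else "participant_id"
  dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      rmse = sqrt(mean((.data$bid - .data$true_value)^2)),
      n_trials = dplyr::n(), .groups = "drop"
    )
}

#' Task-order contrasts with default Bayes factors
#'
#' Paired JZS Bayes-factor t tests of the effect of task order (recall-first
#' RE vs evaluation-first ER) on per-participant recall accuracy (proportion
#' of items recalled) and on WTP accuracy (RMSE). Participants missing
#' either condition are dropped.
#'
#' @param dataset A long-format trial table.
#' @param rscale Cauchy prior scale, default sqrt(2)/2.
#' @return A tibble with `measure`, condition means, `bf10`, and `label`.
#' @export
task_order_contrasts <- function(dataset, rscale = sqrt(2) / 2) {
  sc <- recall_scores(dataset)
  acc <- dataset |>
    dplyr::mutate(prop = rowMeans(sc$correct)) |>
    dplyr::filter(sc$attempted) |>
    dplyr::group_by(.data$participant_id, .data$task_order) |>
    dplyr::summarise(value = mean(.data$prop), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "task_order", values_from = "value")
  rmse <- wtp_rmse(dataset, by_order = TRUE) |>
    tidyr::pivot_wider(names_from = "task_order", values_from = "rmse",
                       id_cols = "participant_id")
  row_for <- function(wide, measure) {
    wide <- wide[complete.cases(wide[, c("RE", "ER")]), ]
    bf <- jzs_ttest_bf(wide$RE, wide$ER, paired = TRUE, rscale = rscale)
    tibble::tibble(
      measure = measure, mean_RE = mean(wide$RE), mean_ER = mean(wide$ER),
      n = nrow(wide), bf10 = bf$bf10, label = bf$label
    )
  }
  dplyr::bind_rows(
    row_for(acc, "recall_accuracy"),
    row_for(rmse, "wtp_rmse")
  )
}
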