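#' Generate one stimulus sequence
#'
#' Draws a seven-item sequence of integer stimulus values in Galactic Credits
#' (GC). The sequence mean is first drawn uniformly from the integers 40 to 70;
#' the seven values are then drawn independently and uniformly (with
#' replacement) from the integers within +/- 29 of that mean, so every
#' per-sequence generating distribution is exactly 58 wide and all values lie
#' in \[11, 99\]. Within-sequence variability is therefore large relative to
#' between-sequence variability.
#'
#' Uses the current R random number generator state.
#'
#' @return A list of class `releval_sequence` with elements `values` (integer
#'   vector of length 7), `dist_mean`, `dist_lo`, `dist_hi` (integers, the
#'   generating distribution's mean and bounds) and `true_value` (the
#'   arithmetic mean of `values`, the sequence's currency value).
#' @export
#' @examples
#' set.seed(1)
#' s <- generate_sequence()
#' s$true_value == mean(s$values)
generate_sequence <- function() {
  dist_mean <- sample(40:70, 1)
  lo <- dist_mean - 29L
  hi <- dist_mean + 29L
  values <- sample(seq.int(lo, hi), 7, replace = TRUE)
  structure(
    list(
      values = as.integer(values),
      dist_mean = as.integer(dist_mean),
      dist_lo = as.integer(lo),
      dist_hi = as.integer(hi),
      true_value = mean(values)
    ),
    class = "releval_sequence"
  )
}

#' Serial-position recall parameters
#'
#' Parameterises the recall simulator: an independent per-position recall
#' probability profile, an attenuation factor applied to the last two
#' positions when recall follows evaluation (ER order, effectively delayed
#' recall with reduced recency), a Poisson intrusion rate, and a cap on the
#' number of reported items.
#'
#' The default profile has one-item primacy and graded recency over the last
#' two positions, the qualitative shape expected for immediate free recall of
#' seven-item lists.
#'
#' @param p_recall Numeric vector of 7 per-position recall probabilities.
#' @param recency_attenuation_er Multiplier in \[0, 1\] applied to the last two
#'   positions' probabilities when the task order is `"ER"`.
#' @param intrusion_rate Expected number of intrusions (reports of values not
#'   presented) per trial; must be >= 0.
#' @param max_outputs Maximum number of reported items per trial.
#' @return A list of class `releval_spc_params`.
#' @export
spc_params <- function(p_recall = c(0.50, 0.42, 0.38, 0.38, 0.40, 0.55, 0.70),
                       recency_attenuation_er = 0.6,
                       intrusion_rate = 0.3,
                       max_outputs = 8L) {
  if (length(p_recall) != 7) stop("p_recall must have length 7", call. = FALSE)
  assert_prob(p_recall, "p_recall")
  assert_prob(recency_attenuation_er, "recency_attenuation_er")
  if (!is.finite(intrusion_rate) || intrusion_rate < 0) {
    stop("intrusion_rate must be >= 0", call. = FALSE)
  }
  structure(
    list(
      p_recall = as.numeric(p_recall),
      recency_attenuation_er = as.numeric(recency_attenuation_er),
      intrusion_rate = as.numeric(intrusion_rate),
      max_outputs = as.integer(max_outputs)
    ),
    class = "releval_spc_params"
  )
}

#' Simulate free recall of a sequence
#'
#' Each serial position is recalled independently with its probability from
#' `spc`; under ER order (evaluation first, so recall is delayed) the last two
#' positions are attenuated by `spc$recency_attenuation_er`. A
#' Poisson-distributed number of intrusions is drawn uniformly from the
#' sequence's generating range, excluding the presented values so that
#' correctness scoring of synthetic data is unambiguous. Output order is
#' randomised and the total number of reports is capped at `spc$max_outputs`.
#'
#' @param sequence A `releval_sequence`.
#' @param spc A [spc_params()] object.
#' @param order Task order, `"RE"` (recall first) or `"ER"` (evaluation first).
#' @return Integer vector of reported values in output order (possibly empty).
#' @export
simulate_recall <- function(sequence, spc, order = c("RE", "ER")) {
  order <- match.arg(order)
  p <- spc$p_recall
  if (order == "ER") p[6:7] <- p[6:7] * spc$recency_attenuation_er
  recalled <- sequence$values[runif(7) < p]
  n_intr <- rpois(1, spc$intrusion_rate)
  if (n_intr > 0) {
    pool <- setdiff(seq.int(sequence$dist_lo, sequence$dist_hi), sequence$values)
    n_intr <- min(n_intr, length(pool))
    intrusions <- if (n_intr > 0) sample(pool, n_intr) else integer(0)
  } else {
    intrusions <- integer(0)
  }
  reports <- c(recalled, intrusions)
  if (length(reports) > 1) reports <- sample(reports)
  if (length(reports) > spc$max_outputs) reports <- reports[seq_len(spc$max_outputs)]
  as.integer(reports)
}

#' Generating parameters for a data-generating evaluation model
#'
#' Bundles the population intercept, participant-intercept spread, slopes,
#' temporal-difference learning rate and residual spread used to simulate
#' willingness-to-pay bids from one of the four candidate models. Slope
#' defaults are the fitted posterior means reported for these models
#' (recalled 0.541, presented 0.936, both 0.41/0.54); the residual and
#' participant spreads default to 3 GC, a strong-signal regime in which the
#' generating model is clearly identifiable. Intercepts default to values
#' that centre simulated bids near 55 GC so that clipping to the response
#' range is rare.
#'
#' @param model_id One of `"recalled"`, `"presented"`, `"both"`, `"td"`.
#' @param b0 Population intercept (GC). Default depends on `model_id`.
#' @param tau Between-participant intercept spread (GC), >= 0.
#' @param beta_recall,beta_presented Slopes on the recalled-items and
#'   presented-items means (used by the models that include them).
#' @param alpha Temporal-difference learning rate in \[0, 1\] (`"td"` only).
#' @param sigma Residual spread of bids (GC), > 0.
#' @return A list of class `releval_gen_params`.
#' @export
gen_params <- function(model_id = c("recalled", "presented", "both", "td"),
                       b0 = NULL, tau = 3, beta_recall = 0.541,
                       beta_presented = 0.936, alpha = 0.7, sigma = 3) {
  model_id <- match.arg(model_id)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0", call. = FALSE)
  assert_prob(alpha, "alpha")
  if (model_id == "both") {
    beta_recall <- if (missing(beta_recall)) 0.41 else beta_recall
    beta_presented <- if (missing(beta_presented)) 0.54 else beta_presented
  }
  if (is.null(b0)) {
    # centre bids near the grand mean stimulus value of 55 GC
    b0 <- switch(model_id,
      recalled = 55 * (1 - beta_recall),
      presented = 55 * (1 - beta_presented),
      both = 55 * (1 - beta_recall - beta_presented),
      td = 55 * (1 - beta_presented)
    )
  }
  structure(
    list(
      model_id = model_id, b0 = b0, tau = tau,
      beta_recall = beta_recall, beta_presented = beta_presented,
      alpha = alpha, sigma = sigma
    ),
    class = "releval_gen_params"
  )
}

#' Simulate a willingness-to-pay bid
#'
#' Produces one bid from the generating model in `params`: intercept plus
#' participant intercept plus the model's linear term in its predictor(s)
#' plus Gaussian noise, clipped to the response range \[0, 100\] GC.
#'
#' @param sequence A `releval_sequence`.
#' @param recall Integer vector of reported values (output order).
#' @param params A [gen_params()] object.
#' @param participant_intercept The participant's intercept deviation (GC).
#' @return A bid in \[0, 100\] GC.
#' @export
simulate_bid <- function(sequence, recall, params, participant_intercept = 0) {
  pred <- switch(params$model_id,
    recalled = {
      if (length(recall) == 0) {
        stop("recalled-model bid requires a non-empty recall set", call. = FALSE)
      }
      params$beta_recall * mean(recall)
    },
    presented = params$beta_presented * presented_predictor(sequence),
    both = {
      if (length(recall) == 0) {
        stop("both-model bid requires a non-empty recall set", call. = FALSE)
      }
      params$beta_recall * mean(recall) +
        params$beta_presented * presented_predictor(sequence)
    },
    td = params$beta_presented * td_value(sequence$values, params$alpha)
  )
  bid <- params$b0 + participant_intercept + pred + rnorm(1, 0, params$sigma)
  min(max(bid, 0), 100)
}

#' Becker-DeGroot-Marschak auction payoff
#'
#' Applies the BDM payoff rule for one trial. The participant holds an
#' endowment of 100 GC. If the bid falls below the randomly drawn selling
#' price no purchase occurs and the participant keeps the endowment. If the
#' bid is at or above the selling price, the sequence is bought at the
#' selling price and the earnings are the remaining endowment plus the
#' sequence's currency value (its true mean). Since only the price, never the
#' bid, sets the amount paid, expected earnings are maximised by bidding the
#' believed true value: the mechanism is incentive compatible.
#'
#' @param bid Bid(s) in \[0, 100\] GC.
#' @param selling_price Randomly drawn selling price(s) (GC); drawn uniformly
#'   from the range of sequence means, \[40, 70\], in the task.
#' @param true_value The sequence's currency value (mean of its 7 values).
#' @param endowment Per-trial endowment, 100 GC.
#' @return Earnings in GC (vectorised over its arguments).
#' @export
#' @examples
#' bdm_payoff(30, 55, 60) # no purchase: keeps the 100 GC endowment
#' bdm_payoff(70, 55, 60) # buys at 55: 100 - 55 + 60 = 105
bdm_payoff <- function(bid, selling_price, true_value, endowment = 100) {
  if (any(bid < 0 | bid > 100)) {
    stop("bid outside the required range [0, 100]", call. = FALSE)
  }
  ifelse(bid < selling_price, endowment, endowment - selling_price + true_value)
}

#' Draw BDM selling prices
#'
#' Selling prices are uniform on \[40, 70\] GC, the range of sequence means
#' used in the task. The distribution is continuous, so a tie between bid and
#' price has probability zero; ties are resolved as a purchase.
#'
#' @param n Number of prices.
#' @return Numeric vector of prices (GC).
#' @export
draw_selling_price <- function(n = 1) runif(n, 40, 70)

#' Generate a synthetic experiment
#'
#' Simulates `n_participants` participants, each completing 32 trials with a
#' balanced, randomly ordered assignment of 16 recall-first (RE) and 16
#' evaluation-first (ER) trials. Participant intercepts are drawn with spread
#' `gen_params$tau`; each trial gets a fresh sequence, a simulated recall set,
#' a bid from the generating model, a uniformly drawn selling price and the
#' BDM earnings. For generating models whose predictor needs a recall
#' (recalled, both), trials whose simulated recall set is empty are
#' re-simulated so the predictor is always defined.
#'
#' The result is a pure function of (`gen_params`, `spc`, `n_participants`,
#' `seed`): the same seed yields an identical table.
#'
#' @param n_participants Number of participants (>= 1).
#' @param gen_params A [gen_params()] object naming the generating model.
#' @param spc A [spc_params()] object.
#' @param seed Integer seed controlling all randomness.
#' @return A tibble with one row per trial: `participant_id`, `trial_index`,
#'   `task_order`, stimulus values `v1`..`v7`, `recalls` (semicolon-delimited
#'   reported values in output order; `""` if none), `bid`, `selling_price`,
#'   `earnings`.
#' @export
generate_dataset <- function(n_participants, gen_params = gen_params("presented"),
                             spc = spc_params(), seed = 1) {
  stopifnot(n_participants >= 1)
  withr::with_seed(seed, {
    needs_recall <- gen_params$model_id %in% c("recalled", "both")
    u <- rnorm(n_participants, 0, gen_params$tau)
    rows <- vector("list", n_participants * 32L)
    k <- 0L
    for (j in seq_len(n_participants)) {
      orders <- sample(rep(c("RE", "ER"), each = 16L))
      for (t in 1:32) {
        sq <- generate_sequence()
        rec <- simulate_recall(sq, spc, orders[t])
        if (needs_recall) {
          tries <- 0L
          while (length(rec) == 0) {
            tries <- tries + 1L
            if (tries > 1000L) {
              stop("recall simulator produced 1000 empty recall sets in a row; ",
                   "p_recall/intrusion_rate too low for a recall-based generator",
                   call. = FALSE)
            }
            rec <- simulate_recall(sq, spc, orders[t])
          }
        }
        bid <- simulate_bid(sq, rec, gen_params, u[j])
        price <- draw_selling_price(1)
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          participant_id = j,
          trial_index = t,
          task_order = orders[t],
          !!!setNames(as.list(sq$values), paste0("v", 1:7)),
          recalls = paste(rec, collapse = ";"),
          bid = bid,
          selling_price = price,
          earnings = bdm_payoff(bid, price, sq$true_value)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Parse a semicolon-delimited recall field
#'
#' @param recalls Character vector of recall fields (`"50;61"`; `""` means an
#'   attempted trial with no reports; `NA` means the recall task was not
#'   completed).
#' @return A list of integer vectors (`NULL` for `NA` fields).
#' @export
parse_recalls <- function(recalls) {
  lapply(recalls, function(r) {
    if (is.na(r)) return(NULL)
    if (!nzchar(r)) return(integer(0))
    as.integer(strsplit(r, ";", fixed = TRUE)[[1]])
  })
}

#' Write / read a long-format trial table
#'
#' The on-disk format is one row per trial with columns `participant_id`,
#' `trial_index`, `task_order`, `v1`..`v7`, `recalls` (semicolon-delimited,
#' output order), `bid`, `selling_price`, `earnings`. Missing bids or
#' unattempted recalls are written as the literal `NA`; an empty `recalls`
#' string is an attempted recall with no reports. `format = "json"` writes
#' the same records as a JSON array of row objects.
#'
#' @param dataset A trial table as returned by [generate_dataset()].
#' @param path Output (input) file path.
#' @param format `"csv"` or `"json"`.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns the trial tibble.
#' @export
write_trial_table <- function(dataset, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(dataset, path, na = "NA")
  } else {
    jsonlite::write_json(dataset, path, dataframe = "rows", na = "string",
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    dat <- readr::read_csv(
      path, na = "NA",
      col_types = readr::cols(
        participant_id = readr::col_double(),
        trial_index = readr::col_integer(),
        task_order = readr::col_character(),
        recalls = readr::col_character(),
        bid = readr::col_double(),
        selling_price = readr::col_double(),
        earnings = readr::col_double(),
        .default = readr::col_integer()
      )
    )
  } else {
    dat <- tibble::as_tibble(jsonlite::fromJSON(path))
    dat$recalls[is.na(dat$recalls) | dat$recalls == "NA"] <- NA_character_
  }
  dat$recalls[!is.na(dat$recalls) & dat$recalls == ""] <- ""
  dat
}
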