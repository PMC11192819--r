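#' Presented-items predictor
#'
#' The predictor of the presented-items model: the arithmetic mean of the
#' seven presented values, i.e. the sequence's true currency value. This is
#' the baseline integrator model with equal weight on every value.
#'
#' @param sequence A `releval_sequence`, or a numeric vector of 7 values.
#' @return The mean presented value (GC).
#' @export
presented_predictor <- function(sequence) {
  values <- if (inherits(sequence, "releval_sequence")) sequence$values else sequence
  mean(values)
}

#' Recalled-items predictor
#'
#' The predictor of the recalled-items model: the mean of all values the
#' participant reported on that trial, including intrusions (false
#' recollections) and duplicate reports. Returns `NA` when nothing was
#' recalled — a missing predictor, not an error.
#'
#' @param reports Integer vector of reported values (output order).
#' @return Mean reported value (GC), or `NA_real_` for an empty recall set.
#' @export
recalled_predictor <- function(reports) {
  if (is.null(reports) || length(reports) == 0) return(NA_real_)
  mean(reports)
}

#' Temporal-difference value of a sequence
#'
#' A running value estimate updated after each stimulus by a learning-rate
#' weighted prediction error: starting from the first presented value, each
#' subsequent value x_t moves the estimate by `alpha * (x_t - V)`. The value
#' after the last presented number — an exponentially recency-weighted
#' average of the sequence — is the model's predictor. `alpha = 0` leaves the
#' first value untouched; `alpha = 1` tracks the most recent value.
#'
#' @param values Numeric vector of presented values in presentation order.
#' @param alpha Learning rate in \[0, 1\].
#' @return The value estimate after the final item (GC).
#' @export
td_value <- function(values, alpha) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  v <- values[1]
  for (t in seq_along(values)[-1]) {
    v <- v + alpha * (values[t] - v)
  }
  v
}

#' Build the shared model-comparison design table
#'
#' Converts a long-format trial table into one design row per usable trial,
#' carrying the response (bid) and every candidate model's trial-level
#' predictor: the presented-items mean, the recalled-items mean, and the raw
#' stimulus values (so the temporal-difference predictor can be recomputed
#' inside the sampler for any learning rate).
#'
#' For model comparison all models must be scored on identical data, so a
#' single shared trial set is used: trials with a missing bid or an empty /
#' unattempted recall set are dropped for every model, making the marginal
#' likelihoods directly comparable.
#'
#' @param dataset A trial table (see [generate_dataset()]).
#' @return A tibble with columns `participant_id`, `trial_index`,
#'   `task_order`, `bid`, `predictor_presented`, `predictor_recalled`,
#'   and `v1`..`v7`.
#' @export
build_design <- function(dataset) {
  vcols <- paste0("v", 1:7)
  rec <- parse_recalls(dataset$recalls)
  out <- dplyr::mutate(
    dataset,
    predictor_presented = rowMeans(dataset[, vcols]),
    predictor_recalled = vapply(rec, recalled_predictor, numeric(1))
  )
  out <- dplyr::filter(
    out,
    !is.na(.data$bid), !is.na(.data$predictor_recalled)
  )
  out <- dplyr::select(
    out, "participant_id", "trial_index", "task_order", "bid",
    "predictor_presented", "predictor_recalled", dplyr::all_of(vcols)
  )
  if (nrow(out) == 0) {
    stop("no usable trials: every trial lacks a bid or a non-empty recall",
         call. = FALSE)
  }
  out
}

#' Export a model's design matrix
#'
#' Writes one row per trial with the response and the named model's
#' predictor column(s) as CSV.
#'
#' @param design A design table from [build_design()].
#' @param model_id One of `"recalled"`, `"presented"`, `"both"`, `"td"`.
#' @param path Output CSV path.
#' @param alpha Learning rate at which to evaluate the TD predictor
#'   (`model_id = "td"` only).
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, model_id, path, alpha = NULL) {
  cols <- c("participant_id", "trial_index", "task_order", "bid")
  out <- design[, cols]
  if (model_id %in% c("recalled", "both")) {
    out$predictor_recalled <- design$predictor_recalled
  }
  if (model_id %in% c("presented", "both")) {
    out$predictor_presented <- design$predictor_presented
  }
  if (model_id == "td") {
    if (is.null(alpha)) stop("alpha is required for the TD design", call. = FALSE)
    xs <- as.matrix(design[, paste0("v", 1:7)])
    out$predictor_td <- apply(xs, 1, td_value, alpha = alpha)
  }
  readr::write_csv(out, path)
  invisible(path)
}
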