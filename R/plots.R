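# Standard figures for the behavioural summaries and the mixture model.

#' Plot serial position curves
#'
#' Mean proportion recalled by serial position and task order, with
#' within-subject SEM error bars (see [spc()]).
#'
#' @param spc_table Output of [spc()].
#' @return A ggplot object.
#' @export
plot_spc <- function(spc_table) {
  ggplot2::ggplot(spc_table,
                  ggplot2::aes(x = .data$position, y = .data$mean_correct,
                               colour = .data$task_order,
                               group = .data$task_order)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_correct - .data$sem,
                   ymax = .data$mean_correct + .data$sem),
      width = 0.15) +
    ggplot2::scale_x_continuous(breaks = 1:7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Serial position", y = "Proportion recalled",
                  colour = "Task order") +
    ggplot2::theme_minimal()
}

#' Plot willingness-to-pay accuracy
#'
#' Mean per-participant RMSE of bids against true sequence values, by task
#' order, with between-participant SEM.
#'
#' @param rmse_table Output of `wtp_rmse(dataset, by_order = TRUE)`.
#' @return A ggplot object.
#' @export
plot_wtp_rmse <- function(rmse_table) {
  summ <- rmse_table |>
    dplyr::group_by(.data$task_order) |>
    dplyr::summarise(mean_rmse = mean(.data$rmse),
                     sem = sd(.data$rmse) / sqrt(dplyr::n()))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$task_order,
                                     y = .data$mean_rmse)) +
    ggplot2::geom_col(width = 0.6, fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_rmse - .data$sem,
                   ymax = .data$mean_rmse + .data$sem), width = 0.15) +
    ggplot2::labs(x = "Task order", y = "WTP RMSE (GC)") +
    ggplot2::theme_minimal()
}

#' Plot per-participant mixture weights
#'
#' Stacked posterior-mean strategy probabilities per participant, ordered by
#' the weight on the recalled-items component.
#'
#' @param fit A `releval_mixture`.
#' @return A ggplot object.
#' @export
plot_mixture <- function(fit) {
  cls <- classify_participants(fit)$assignments
  long <- cls |>
    dplyr::mutate(rank = rank(-.data$theta_recalled, ties.method = "first")) |>
    tidyr::pivot_longer(dplyr::starts_with("theta_"),
                        names_to = "component", values_to = "weight",
                        names_prefix = "theta_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$weight,
                                     fill = .data$component)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "Participant (ordered)",
                  y = "Posterior strategy probability", fill = "Strategy") +
    ggplot2::theme_minimal()
}
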