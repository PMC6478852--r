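#' Plot mean choice percentages by symbol value
#'
#' Recreates the study's choice-phase figure: mean percentage of selections
#' of each symbol (ordered by its expected value, from the 80% LOSS symbol
#' at -80% to the 80% GAIN symbol at +80%), by condition, faceted by choice
#' phase. A monotone rise of choices with symbol value is the signature of
#' expressed reinforcement learning.
#'
#' @param object A `gl_choice_summary` from [choice_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gl_choice_summary <- function(object, ...) {
  ev <- setNames(gl_symbols()$ev, gl_symbols()$symbol)
  long <- object |>
    tidyr::pivot_longer(dplyr::starts_with("choose_"), names_to = "symbol",
                        names_prefix = "choose_", values_to = "choose") |>
    dplyr::mutate(value = 100 * ev[.data$symbol]) |>
    dplyr::group_by(.data$condition, .data$phase, .data$symbol, .data$value) |>
    dplyr::summarise(mean = mean(.data$choose),
                     se = sd(.data$choose) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$mean,
                                     colour = .data$condition,
                                     group = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::facet_wrap(~ .data$phase) +
    ggplot2::labs(x = "Symbol value (%)", y = "Mean % chosen",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' Plot learning curves
#'
#' Mean optimal-response accuracy over learning trials in bins, by
#' condition, with the chance level marked.
#'
#' @param trials Cohort trial tibble.
#' @param bin_width Trials per bin.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(trials, bin_width = 15) {
  learn <- trials |>
    dplyr::filter(.data$phase == "learning") |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::arrange(.data$block, .data$trial_index, .by_group = TRUE) |>
    dplyr::mutate(bin = (dplyr::row_number() - 1) %/% bin_width + 1) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$condition, .data$bin) |>
    dplyr::summarise(accuracy = 100 * mean(.data$optimal), .groups = "drop")
  ggplot2::ggplot(learn, ggplot2::aes(x = .data$bin, y = .data$accuracy,
                                      colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 50, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("Learning trial bin (%d trials)", bin_width),
                  y = "% optimal", colour = "Condition") +
    ggplot2::theme_minimal()
}

#' Plot a model comparison
#'
#' Mean per-unit BIC by model with the winner highlighted.
#'
#' @param object A `gl_model_comparison` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gl_model_comparison <- function(object, ...) {
  d <- object$summary
  d$winner <- !object$tie & d$model == object$winner
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$mean_bic,
                                  fill = .data$winner)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "Mean BIC (lower is better)") +
    ggplot2::theme_minimal()
}
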