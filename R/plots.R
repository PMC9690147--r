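#' Plot a few records per class
#'
#' Normalized waveforms, one facet per record, colored by class — a quick
#' visual check that the three classes carry the expected morphology.
#'
#' @param data EEG dataset tibble.
#' @param n_per_class Records to show per class (default 2).
#' @return A ggplot object.
#' @export
plot_records <- function(data, n_per_class = 2) {
  shown <- data |>
    dplyr::group_by(.data$label) |>
    dplyr::slice_head(n = n_per_class) |>
    dplyr::ungroup()
  long <- shown |>
    dplyr::mutate(t = purrr::map2(.data$samples, .data$fs,
                                  ~ (seq_along(.x) - 1) / .y)) |>
    tidyr::unnest(c("samples", "t"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$samples,
                                     color = .data$label)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~record_id, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "normalized amplitude",
                  color = "class") +
    ggplot2::theme_minimal()
}

#' Pairwise distribution of reconstruction features
#'
#' The clustering view: every pair of features as a colored scatter, the
#' analogue of the feature-distribution panels used to inspect class
#' separation.
#'
#' @param table Feature table tibble (AE features or normalized PCs).
#' @param features Which feature columns to plot (default: all).
#' @return A ggplot object.
#' @export
plot_feature_distribution <- function(table, features = NULL) {
  feats <- features %||% feature_names(table)
  pairs <- utils::combn(feats, 2, simplify = FALSE)
  long <- dplyr::bind_rows(lapply(pairs, function(p) {
    tibble::tibble(pair = paste(p[1], "vs", p[2]),
                   x = table[[p[1]]], y = table[[p[2]]],
                   label = table$label)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$label)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, color = "class") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap for an evaluation report
#'
#' @param object An `eeg_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_y_discrete(limits = rev(eeg_classes())) +
    ggplot2::labs(title = paste0(object$classifier, " (test accuracy ",
                                 format(object$test_accuracy, digits = 3),
                                 ")"),
                  x = "predicted", y = "true class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Importance bar charts
#'
#' Permutation importance (mean accuracy drop, with one-sd error bars)
#' and mean |SHAP| per feature, side by side.
#'
#' @param object An `importance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.importance_report <- function(object, ...) {
  df <- dplyr::bind_rows(
    object$permutation |>
      dplyr::transmute(feature = .data$feature, value = .data$importance,
                       sd = .data$sd, metric = "permutation importance"),
    object$shap_importance |>
      dplyr::transmute(feature = .data$feature,
                       value = .data$mean_abs_shap, sd = NA_real_,
                       metric = "mean |SHAP|"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature,
                                                      .data$value),
                                   y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sd,
                                        ymax = .data$value + .data$sd),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(title = object$classifier, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Training-loss curve of the autoencoder
#'
#' @param object An `eeg_autoencoder`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_autoencoder <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch,
                                             y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "mean training MSE") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
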