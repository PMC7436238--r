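tissue_palette <- function() {
  setNames(grDevices::rgb(t(class_base_rgb())), tissue_classes())
}

#' Track-strip plot of predicted labels over time
#'
#' One horizontal colour strip per track (video, model, or ground truth):
#' the x axis is the frame index, the fill is the predicted tissue class.
#' Instability shows up as rapid colour flicker.
#'
#' @param tracks Tibble with `frame_index`, `label`, and a `track` column
#'   naming the strip each row belongs to (e.g. video id or head).
#' @return A ggplot object.
#' @export
plot_label_tracks <- function(tracks) {
  stopifnot(all(c("frame_index", "label", "track") %in% names(tracks)))
  ggplot2::ggplot(tracks,
                  ggplot2::aes(x = .data$frame_index, y = 1,
                               fill = .data$label)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$track), switch = "y") +
    ggplot2::scale_fill_manual(values = tissue_palette(), drop = FALSE) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "frame", y = NULL, fill = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text.y.left = ggplot2::element_text(angle = 0),
                   panel.grid = ggplot2::element_blank())
}

#' Confusion-matrix heatmap of an evaluation
#'
#' Per-patient-normalized percentages: rows are true labels, columns
#' predicted labels.
#'
#' @param object A `pullback_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pullback_evaluation <- function(object, ...) {
  cm <- object$confusion
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(cm),
                  truth = factor(rownames(cm), rev(tissue_classes()))),
    cols = -"truth", names_to = "pred", values_to = "pct")
  df$pred <- factor(df$pred, tissue_classes())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$pct), "", sprintf("%.1f", .data$pct))),
      size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7bb6",
                                 na.value = "grey90", limits = c(0, 100)) +
    ggplot2::labs(x = "predicted", y = "true", fill = "%") +
    ggplot2::theme_minimal()
}

#' Per-head switch/accuracy summary plot of a cross-validation run
#'
#' @param object A `pullback_cv`.
#' @param ... Unused.
#' @return A ggplot object (mean switches per video by head, with the mean
#'   label accuracy printed above each bar).
#' @export
autoplot.pullback_cv <- function(object, ...) {
  s <- object$summary
  s$head <- factor(s$head, s$head)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$head, y = .data$mean_switches)) +
    ggplot2::geom_col(fill = "#2c7bb6") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$mean_switches - .data$sd_switches),
      ymax = .data$mean_switches + .data$sd_switches), width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", 100 * .data$mean_label_accuracy)),
      vjust = -0.6) +
    ggplot2::labs(x = NULL, y = "mean label switches per video") +
    ggplot2::theme_minimal()
}

#' Training loss curve
#'
#' @param model A trained `pullback_model` with a `history`.
#' @return A ggplot object.
#' @export
plot_loss_history <- function(model) {
  stopifnot(!is.null(model$history))
  ggplot2::ggplot(model$history,
                  ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line(colour = "#2c7bb6") +
    ggplot2::labs(x = "iteration", y = "cross-entropy loss") +
    ggplot2::theme_minimal()
}
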