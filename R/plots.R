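#' Training-loss trace of an autoencoder
#'
#' @param object A `composcore_ae` from [train_ae()].
#' @param ... Unused.
#' @return A ggplot of the dropout-free training loss per epoch (log scale).
#' @export
autoplot.composcore_ae <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$loss_trace), loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "epoch", y = "training MSE (dropout-free)",
      title = sprintf(
        "Autoencoder training (%s, hidden %d)",
        object$architecture$activation, object$architecture$hidden
      )
    ) +
    ggplot2::theme_minimal()
}

#' Per-subject composite arrow plot
#'
#' One horizontal arrow per subject from the composite score under the
#' first condition to the score under the second; stars mark the
#' per-condition group means.
#'
#' @param arrows Arrow data from [arrow_plot_data()] (its `"group_means"`
#'   attribute supplies the mean markers when present).
#' @return A ggplot.
#' @export
plot_arrows <- function(arrows) {
  gm <- attr(arrows, "group_means")
  p <- ggplot2::ggplot(arrows) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$score_from, xend = .data$score_to,
                   y = .data$subject, yend = .data$subject),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.18, "cm")),
      colour = "grey30"
    ) +
    ggplot2::labs(
      x = sprintf("aligned composite score (%s → %s)",
                  arrows$from[1], arrows$to[1]),
      y = "subject"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(gm)) {
    p <- p + ggplot2::geom_vline(
      data = gm,
      ggplot2::aes(xintercept = .data$mean_score, colour = .data$condition),
      linetype = "dashed"
    ) +
      ggplot2::labs(colour = "condition mean")
  }
  p
}

#' Two-component PCA score plane
#'
#' Scatter of the first two component scores, coloured by condition, with
#' stars at the per-condition means.
#'
#' @param object A `composcore_pca` fitted with `n_components >= 2`.
#' @param conditions A vector of condition labels, one per record (e.g. the
#'   cohort's `condition` column).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.composcore_pca <- function(object, conditions = NULL, ...) {
  if (object$n_components < 2) abort("need a 2-component fit to plot the plane")
  df <- tibble(
    PC1 = object$scores[, 1],
    PC2 = object$scores[, 2],
    condition = if (is.null(conditions)) "record" else as.character(conditions)
  )
  means <- df |>
    group_by(.data$condition) |>
    summarise(PC1 = mean(.data$PC1), PC2 = mean(.data$PC2), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$condition)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_point(data = means, shape = 8, size = 4, stroke = 1.2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%% of variance)", 100 * object$variance_fractions[1]),
      y = sprintf("PC2 (%.1f%% of variance)", 100 * object$variance_fractions[2])
    ) +
    ggplot2::theme_minimal()
}
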