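# ggplot2 autoplot methods for the package's result types.

#' Plot a collaboration graph's weight distributions
#'
#' Degree distribution of the nodes and collaboration-count distribution
#' of the edges, side by side.
#'
#' @param object A `collab_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.collab_graph <- function(object, ...) {
  deg <- node_degrees(object)
  dat <- dplyr::bind_rows(
    tibble::tibble(what = "node degree", value = as.numeric(deg)),
    tibble::tibble(
      what = "edge collab_count",
      value = as.numeric(object$edges$collab_count)
    )
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~what, scales = "free") +
    ggplot2::labs(
      x = NULL, y = "count",
      title = "Collaboration network weight distributions"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a metrics report
#'
#' Accuracy@K curves per repeat (thin lines) with the mean (bold), plus
#' AUC and F1 per repeat as points.
#'
#' @param object A `collab_metrics`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.collab_metrics <- function(object, ...) {
  long <- tidy(object)
  acc <- long[grepl("^acc_at_", long$metric), ]
  acc$k <- as.integer(sub("acc_at_", "", acc$metric))
  mean_acc <- acc |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line(
      ggplot2::aes(group = .data$run),
      alpha = 0.35, colour = "grey50"
    ) +
    ggplot2::geom_line(
      data = mean_acc, colour = "firebrick", linewidth = 1.1
    ) +
    ggplot2::scale_x_continuous(breaks = sort(unique(acc$k))) +
    ggplot2::labs(
      x = "k", y = paste0("Accuracy@K (", object$config$acc_mode, ")"),
      title = "Top-K recommendation accuracy across repeats"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param object A `collab_gnn`.
#' @param ... Unused.
#' @return A ggplot object of train and monitored loss per epoch.
#' @export
autoplot.collab_gnn <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$history, -"epoch",
    names_to = "loss", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$epoch, y = .data$value, colour = .data$loss
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = object$best_epoch, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "epoch", y = "binary cross-entropy",
      title = "Link-prediction training history"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a recommendation ranking
#'
#' @param object A `collab_ranking`.
#' @param ... Unused.
#' @return A ggplot lollipop chart of candidate scores, existing partners
#'   highlighted.
#' @export
autoplot.collab_ranking <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$candidate <- factor(dat$candidate, levels = rev(dat$candidate))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$score, y = .data$candidate,
    colour = .data$existing_partner
  )) +
    ggplot2::geom_segment(ggplot2::aes(
      x = 0, xend = .data$score, yend = .data$candidate
    )) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = "collaboration score", y = NULL,
      colour = "existing partner",
      title = paste0("Top recommendations for ", attr(object, "target"))
    ) +
    ggplot2::theme_minimal()
}
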