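# broom-style tidiers for the package's result objects.

#' Tidy a collaboration graph into its edge table
#'
#' @param x A `collab_graph`.
#' @param ... Unused.
#' @return The edge tibble (`u`, `v`, `collab_count`, `intervention_raw`,
#'   `intervention_norm`).
#' @export
tidy.collab_graph <- function(x, ...) {
  x$edges
}

#' One-row summary of a collaboration graph
#'
#' @param x A `collab_graph`.
#' @param ... Unused.
#' @return Tibble with node/edge counts, total trial participations, total
#'   collaboration weight and edge density.
#' @export
glance.collab_graph <- function(x, ...) {
  n <- nrow(x$nodes)
  tibble::tibble(
    n_nodes = n,
    n_edges = nrow(x$edges),
    total_trial_count = sum(x$nodes$trial_count),
    total_collab_count = sum(x$edges$collab_count),
    density = if (n >= 2) nrow(x$edges) / choose(n, 2) else NA_real_
  )
}

#' Tidy a metrics report into long format
#'
#' @param x A `collab_metrics`.
#' @param ... Unused.
#' @return Long tibble with columns `run`, `seed`, `metric`, `value`.
#' @export
tidy.collab_metrics <- function(x, ...) {
  tidyr::pivot_longer(
    x$per_repeat,
    cols = -c("run", "seed"),
    names_to = "metric", values_to = "value"
  )
}

#' One-row summary of a metrics report
#'
#' @param x A `collab_metrics`.
#' @param ... Unused.
#' @return Tibble with one `<metric>_mean` / `<metric>_sd` pair per metric
#'   plus the repeat count.
#' @export
glance.collab_metrics <- function(x, ...) {
  out <- tibble::tibble(n_repeats = nrow(x$per_repeat))
  for (i in seq_len(nrow(x$summary))) {
    out[[paste0(x$summary$metric[[i]], "_mean")]] <- x$summary$mean[[i]]
    out[[paste0(x$summary$metric[[i]], "_sd")]] <- x$summary$sd[[i]]
  }
  out
}

#' Tidy a trained link-prediction fit into its loss history
#'
#' @param x A `collab_gnn`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.collab_gnn <- function(x, ...) {
  x$history
}

#' One-row summary of a trained fit
#'
#' @param x A `collab_gnn`.
#' @param ... Unused.
#' @return Tibble with encoder, layer/width, epochs run, best epoch and
#'   best monitored loss.
#' @export
glance.collab_gnn <- function(x, ...) {
  tibble::tibble(
    encoder = x$model_config$encoder,
    n_layers = x$model_config$n_layers,
    hidden_dim = x$model_config$hidden_dim,
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss
  )
}
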