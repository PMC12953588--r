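# End-to-end experiment: build -> features -> split -> negatives -> train
# -> evaluate, repeated over seeds.

#' Experiment configuration
#'
#' Bundles every knob of [run_experiment()]. Defaults follow the reference
#' setup: temporal split, two GCN layers, 128-dimensional features and
#' hidden width, learning rate 0.001, L2 1e-5, 100 epochs with early
#' stopping, 10 repeats, 1:1 negative sampling.
#'
#' @param keywords Optional condition keywords; when given, records are
#'   filtered with [filter_by_condition()] first.
#' @param split `"temporal"` or `"random"`.
#' @param cutoff_year Last training year for the temporal split.
#' @param test_fraction Test fraction for the random split.
#' @param features `"fused"` (attribute fusion) or `"structure"`
#'   (attribute-free ablation).
#' @param embed_dim Width of the text-embedding provider.
#' @param feature_dim Fused feature width fed to the encoder.
#' @param encoder,hidden_dim,n_layers,use_edge_weights,fuse_edge_attr
#'   Passed to [model_config()].
#' @param learning_rate,l2,max_epochs,patience Passed to [train_config()].
#' @param val_fraction Fraction of training positives carved out per repeat
#'   as the validation set (matched 1:1 with negatives).
#' @param n_repeats Number of independent repeats.
#' @param seed Master seed; every repeat derives its own seeds from it.
#' @param k_max Largest Accuracy@K cutoff reported.
#' @param acc_mode `"normalized"` or `"literal"` Accuracy@K for the report.
#' @param neg_per_user Candidate negatives sampled per test user when
#'   building per-user rankings.
#' @param f1_threshold Probability threshold for the F1 score.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(keywords = NULL,
                              split = c("temporal", "random"),
                              cutoff_year = 2021L,
                              test_fraction = 0.2,
                              features = c("fused", "structure"),
                              embed_dim = 32L,
                              feature_dim = 128L,
                              encoder = c("gcn", "sage"),
                              hidden_dim = 128L,
                              n_layers = 2L,
                              use_edge_weights = TRUE,
                              fuse_edge_attr = TRUE,
                              learning_rate = 0.001,
                              l2 = 1e-5,
                              max_epochs = 100L,
                              patience = 10L,
                              val_fraction = 0.1,
                              n_repeats = 10L,
                              seed = 1L,
                              k_max = 10L,
                              acc_mode = c("normalized", "literal"),
                              neg_per_user = 20L,
                              f1_threshold = 0.5) {
  structure(
    list(
      keywords = keywords,
      split = match.arg(split),
      cutoff_year = as.integer(cutoff_year),
      test_fraction = test_fraction,
      features = match.arg(features),
      embed_dim = as.integer(embed_dim),
      feature_dim = as.integer(feature_dim),
      encoder = match.arg(encoder),
      hidden_dim = as.integer(hidden_dim),
      n_layers = as.integer(n_layers),
      use_edge_weights = isTRUE(use_edge_weights),
      fuse_edge_attr = isTRUE(fuse_edge_attr),
      learning_rate = learning_rate,
      l2 = l2,
      max_epochs = as.integer(max_epochs),
      patience = as.integer(patience),
      val_fraction = val_fraction,
      n_repeats = as.integer(n_repeats),
      seed = as.integer(seed),
      k_max = as.integer(k_max),
      acc_mode = match.arg(acc_mode),
      neg_per_user = as.integer(neg_per_user),
      f1_threshold = f1_threshold
    ),
    class = "experiment_config"
  )
}

# Carve a validation subset out of the training positives.
carve_validation <- function(split, val_fraction, seed) {
  n_val <- floor(val_fraction * nrow(split$train_pos))
  if (n_val == 0) {
    return(split)
  }
  rows <- withr::with_seed(seed, sample.int(nrow(split$train_pos), n_val))
  split$val_pos <- split$train_pos[rows, ]
  split$train_pos <- split$train_pos[-rows, ]
  split
}

fill_negatives <- function(graph, split, seed) {
  forbidden <- dplyr::bind_rows(split$train_pos, split$val_pos, split$test_pos)
  split$train_neg <- sample_negatives(
    graph, split$train_pos, forbidden, derive_seed(seed, 1)
  )
  forbidden <- dplyr::bind_rows(forbidden, split$train_neg)
  split$val_neg <- sample_negatives(
    graph, split$val_pos, forbidden, derive_seed(seed, 2)
  )
  forbidden <- dplyr::bind_rows(forbidden, split$val_neg)
  split$test_neg <- sample_negatives(
    graph, split$test_pos, forbidden, derive_seed(seed, 3)
  )
  split
}

# Per-user rankings over that user's test positives plus sampled
# non-partner candidates; returns list(rankings=, relevants=).
user_rankings <- function(graph, H, split, neg_per_user, seed) {
  nm <- graph$nodes$name
  users <- sort_c(unique(c(split$test_pos$u, split$test_pos$v)))
  adj_keys <- pair_keys(graph$edges)
  rankings <- list()
  relevants <- list()
  for (ui in seq_along(users)) {
    u <- users[[ui]]
    rel <- sort_c(unique(c(
      split$test_pos$v[split$test_pos$u == u],
      split$test_pos$u[split$test_pos$v == u]
    )))
    others <- setdiff(nm, c(u, rel))
    cand_pairs <- canonical_pairs(rep(u, length(others)), others)
    non_adj <- others[!(pair_keys(cand_pairs) %in% adj_keys)]
    n_draw <- min(neg_per_user, length(non_adj))
    negs <- if (n_draw > 0) {
      withr::with_seed(
        derive_seed(seed, 100 + ui),
        sample(non_adj, n_draw)
      )
    } else {
      character()
    }
    cands <- c(rel, negs)
    sc <- score_edges(H, tibble::tibble(u = rep(u, length(cands)), v = cands))
    ord <- order(-sc, cands, method = "radix")
    rankings[[u]] <- cands[ord]
    relevants[[u]] <- rel
  }
  list(rankings = rankings, relevants = relevants)
}

run_one_repeat <- function(records, config, seed) {
  # 1. training-visible records and graph
  if (config$split == "temporal") {
    if (all(is.na(records$year))) {
      stop("Temporal split requires registration years", call. = FALSE)
    }
    train_records <- records[!is.na(records$year) &
      records$year <= config$cutoff_year, ]
    graph <- build_graph(train_records)
    split <- temporal_split(records, config$cutoff_year)
    # test pairs must connect nodes the training graph knows about
    keep <- split$test_pos$u %in% graph$nodes$name &
      split$test_pos$v %in% graph$nodes$name
    split$test_pos <- split$test_pos[keep, ]
  } else {
    graph <- build_graph(records)
    split <- random_split_with_isolated(graph, config$test_fraction, seed)
  }
  if (nrow(split$test_pos) == 0) {
    stop("Split produced no test positives", call. = FALSE)
  }

  split <- carve_validation(split, config$val_fraction, derive_seed(seed, 4))
  split <- fill_negatives(graph, split, seed)
  validate_edge_split(split)

  # 2. features (train-visible records only, by construction of `graph`)
  X <- if (config$features == "fused") {
    fuse_node_features(
      graph,
      provider = default_text_encoder(config$embed_dim, seed = config$seed),
      out_dim = config$feature_dim,
      seed = config$seed
    )
  } else {
    structure_node_features(graph)
  }

  mc <- model_config(
    encoder = config$encoder, n_layers = config$n_layers,
    hidden_dim = config$hidden_dim,
    use_edge_weights = config$use_edge_weights,
    fuse_edge_attr = config$fuse_edge_attr
  )
  tc <- train_config(
    learning_rate = config$learning_rate, l2 = config$l2,
    max_epochs = config$max_epochs, patience = config$patience,
    seed = seed
  )
  fit <- train_link_model(X, graph, split, mc, tc)

  pos_s <- score_edges(fit$H, split$test_pos)
  neg_s <- score_edges(fit$H, split$test_neg)
  auc <- auc_score(pos_s, neg_s)
  f1 <- f1_score(
    c(pos_s, neg_s),
    c(rep(1, length(pos_s)), rep(0, length(neg_s))),
    threshold = config$f1_threshold
  )

  ur <- user_rankings(graph, fit$H, split, config$neg_per_user, seed)
  acc <- accuracy_curve(ur$rankings, ur$relevants, config$k_max, config$acc_mode)
  lit <- accuracy_curve(ur$rankings, ur$relevants, config$k_max, "literal")

  row <- tibble::tibble(seed = seed, auc = auc, f1 = f1)
  for (k in acc$k) row[[paste0("acc_at_", k)]] <- acc$accuracy[[k]]
  for (k in lit$k) row[[paste0("acc_literal_at_", k)]] <- lit$accuracy[[k]]
  list(metrics = row, fit = fit, split = split, graph = graph)
}

#' Run the full repeated link-prediction experiment
#'
#' Executes the whole pipeline — graph construction, feature fusion, edge
#' split, 1:1 negative sampling, encoder training, evaluation — once per
#' repeat, each repeat under its own derived seed, and aggregates AUC, F1
#' and Accuracy@1..k over repeats. Per-user rankings for Accuracy@K are
#' computed over each test user's test positives plus sampled
#' non-collaborating candidates.
#'
#' @param records A canonicalized trial-record tibble.
#' @param config An [experiment_config()].
#' @return A `collab_metrics` report: `per_repeat` (one row per repeat,
#'   with `acc_at_*` in the configured mode and `acc_literal_at_*` raw hit
#'   counts alongside), `summary` (mean and sd per metric) and the
#'   `config`.
#' @export
run_experiment <- function(records, config = experiment_config()) {
  if (!is.null(config$keywords)) {
    records <- filter_by_condition(records, config$keywords)
  }
  reps <- lapply(seq_len(config$n_repeats), function(r) {
    seed_r <- derive_seed(config$seed, r)
    res <- tryCatch(
      run_one_repeat(records, config, seed_r),
      error = function(e) {
        stop("Repeat ", r, " failed: ", conditionMessage(e), call. = FALSE)
      }
    )
    res$metrics$run <- r
    res$metrics
  })
  per_repeat <- dplyr::bind_rows(reps) |>
    dplyr::relocate("run", "seed")

  metric_cols <- setdiff(names(per_repeat), c("run", "seed"))
  summary <- tibble::tibble(
    metric = metric_cols,
    mean = vapply(
      metric_cols, function(m) mean(per_repeat[[m]]), numeric(1),
      USE.NAMES = FALSE
    ),
    sd = vapply(
      metric_cols, function(m) stats::sd(per_repeat[[m]]), numeric(1),
      USE.NAMES = FALSE
    )
  )
  structure(
    list(per_repeat = per_repeat, summary = summary, config = config),
    class = "collab_metrics"
  )
}

#' @export
print.collab_metrics <- function(x, ...) {
  cat(
    "<collab_metrics> ", nrow(x$per_repeat), " repeat(s), ",
    x$config$encoder, " encoder, ", x$config$features, " features, ",
    x$config$split, " split\n",
    sep = ""
  )
  top <- x$summary[x$summary$metric %in% c("auc", "f1"), ]
  for (i in seq_len(nrow(top))) {
    cat(sprintf(
      "  %-4s mean %.4f (sd %.4f)\n",
      top$metric[[i]], top$mean[[i]], top$sd[[i]]
    ))
  }
  invisible(x)
}

#' Write a metrics report as JSON and/or CSV
#'
#' The JSON payload contains the configuration, the per-repeat table and
#' the summary; it is a pure function of the report, so identical reports
#' produce byte-identical files.
#'
#' @param report A `collab_metrics`.
#' @param path Output path (`.json`).
#' @param csv_path Optional flat CSV path (one row per repeat).
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path, csv_path = NULL) {
  payload <- list(
    config = unclass(report$config)[!vapply(
      unclass(report$config), is.null, logical(1)
    )],
    per_repeat = report$per_repeat,
    summary = report$summary
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    readr::write_csv(report$per_repeat, csv_path, progress = FALSE)
  }
  invisible(path)
}
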