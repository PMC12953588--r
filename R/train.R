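# Link-prediction training: binary cross-entropy on sigmoid(dot scores),
# hand-derived backprop for the two fixed encoder families, Adam updates.

#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param l2 L2 regularization strength on all weights (default 1e-5).
#' @param max_epochs Epoch budget (default 100).
#' @param patience Early-stopping patience on validation loss, in epochs
#'   (default 10; must not exceed `max_epochs`).
#' @param seed Integer seed controlling weight initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, l2 = 1e-5,
                         max_epochs = 100L, patience = 10L, seed = 1L) {
  stopifnot(
    learning_rate > 0, l2 >= 0, max_epochs >= 1,
    patience >= 1, patience <= max_epochs
  )
  structure(
    list(
      learning_rate = learning_rate, l2 = l2,
      max_epochs = as.integer(max_epochs),
      patience = as.integer(patience), seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

# Mean BCE of sigmoid(scores) against 0/1 labels.
bce_loss <- function(scores, labels) {
  mean(softplus(scores) - labels * scores)
}

edge_score_grad <- function(H, idx, labels) {
  s <- rowSums(H[idx[, 1], , drop = FALSE] * H[idx[, 2], , drop = FALSE])
  g <- (plogis(s) - labels) / length(s)
  dH <- matrix(0, nrow(H), ncol(H))
  acc <- function(dH, at, contrib) {
    piece <- rowsum(contrib, group = at)
    rows <- as.integer(rownames(piece))
    dH[rows, ] <- dH[rows, ] + piece
    dH
  }
  dH <- acc(dH, idx[, 1], g * H[idx[, 2], , drop = FALSE])
  dH <- acc(dH, idx[, 2], g * H[idx[, 1], , drop = FALSE])
  list(scores = s, dH = dH)
}

# Backward pass through the encoder; returns gradients shaped like
# state$layers.
encode_backward <- function(fw, P, state, dH, config = state$config) {
  L <- config$n_layers
  grads <- vector("list", L)
  dHl <- dH
  for (l in rev(seq_len(L))) {
    dZ <- if (l < L) dHl * (fw$Zs[[l]] > 0) else dHl
    Hin <- fw$Hs[[l]]
    if (config$encoder == "gcn") {
      PH <- P %*% Hin
      grads[[l]] <- list(W = crossprod(PH, dZ))
      dHl <- P %*% (dZ %*% t(state$layers[[l]]$W)) # P symmetric
    } else {
      PH <- P %*% Hin
      grads[[l]] <- list(
        W_self = crossprod(Hin, dZ),
        W_nbr = crossprod(PH, dZ)
      )
      dHl <- dZ %*% t(state$layers[[l]]$W_self) +
        crossprod(P, dZ %*% t(state$layers[[l]]$W_nbr))
    }
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(lay) lapply(lay, function(W) {
    list(m = W * 0, v = W * 0)
  }))
}

adam_step <- function(state, grads, opt, t, lr, l2,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (l in seq_along(state$layers)) {
    for (nm in names(state$layers[[l]])) {
      g <- grads[[l]][[nm]] + 2 * l2 * state$layers[[l]][[nm]]
      mo <- opt[[l]][[nm]]
      mo$m <- b1 * mo$m + (1 - b1) * g
      mo$v <- b2 * mo$v + (1 - b2) * g^2
      mhat <- mo$m / (1 - b1^t)
      vhat <- mo$v / (1 - b2^t)
      state$layers[[l]][[nm]] <- state$layers[[l]][[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      opt[[l]][[nm]] <- mo
    }
  }
  list(state = state, opt = opt)
}

#' Train a link-prediction model
#'
#' Minimizes the mean binary cross-entropy of `sigmoid(h_u . h_i)` with
#' labels 1 on `train_pos` and 0 on `train_neg`, plus an L2 penalty on all
#' weights, using Adam. Message passing uses only the training positive
#' edges (weights taken from the graph), so no validation or test edge
#' leaks into propagation. Training stops early when the validation loss
#' has not improved for `patience` epochs (falling back to the training
#' loss when the split has no validation pairs) and the best-epoch weights
#' are restored.
#'
#' @param X Node feature matrix, rows in the graph's node order.
#' @param graph A `collab_graph`.
#' @param split An `edge_split` whose train (and optionally val) sets are
#'   filled 1:1.
#' @param model_config A [model_config()].
#' @param train_cfg A [train_config()].
#' @return A `collab_gnn` fit: the best `state`, the final embeddings `H`,
#'   the propagation matrix, and a per-epoch `history` tibble with
#'   `train_loss` and `val_loss`.
#' @export
train_link_model <- function(X, graph, split,
                             model_config = ctcollab::model_config(),
                             train_cfg = train_config()) {
  validate_edge_split(split, require_negatives = FALSE)
  if (nrow(split$train_pos) == 0 || nrow(split$train_neg) == 0) {
    stop("Training requires non-empty train_pos and train_neg", call. = FALSE)
  }
  A <- restricted_adjacency(
    graph, split$train_pos,
    use_edge_weights = model_config$use_edge_weights,
    fuse_edge_attr = model_config$fuse_edge_attr
  )
  P <- propagation_matrix(A, model_config)
  if (is.null(rownames(X)) || !identical(rownames(X), graph$nodes$name)) {
    stop("Feature matrix rows must align with graph node order", call. = FALSE)
  }

  tr_idx <- edges_to_index(rbind(split$train_pos, split$train_neg), X)
  tr_lab <- c(rep(1, nrow(split$train_pos)), rep(0, nrow(split$train_neg)))
  has_val <- nrow(split$val_pos) > 0 && nrow(split$val_neg) > 0
  if (has_val) {
    va_idx <- edges_to_index(rbind(split$val_pos, split$val_neg), X)
    va_lab <- c(rep(1, nrow(split$val_pos)), rep(0, nrow(split$val_neg)))
  }

  state <- init_model_state(ncol(X), model_config, seed = train_cfg$seed)
  opt <- adam_init(state$layers)
  l2_pen <- function(st) {
    train_cfg$l2 * sum(vapply(
      st$layers,
      function(lay) sum(vapply(lay, function(W) sum(W^2), numeric(1))),
      numeric(1)
    ))
  }

  best_state <- state
  best_loss <- Inf
  best_epoch <- 0L
  since_best <- 0L
  hist_train <- hist_val <- numeric(train_cfg$max_epochs)

  for (epoch in seq_len(train_cfg$max_epochs)) {
    fw <- encode_forward(X, P, state)
    eg <- edge_score_grad(fw$H, tr_idx, tr_lab)
    train_loss <- bce_loss(eg$scores, tr_lab) + l2_pen(state)
    if (!is.finite(train_loss)) {
      stop("Non-finite training loss at epoch ", epoch, call. = FALSE)
    }
    grads <- encode_backward(fw, P, state, eg$dH)
    upd <- adam_step(
      state, grads, opt, epoch,
      lr = train_cfg$learning_rate, l2 = train_cfg$l2
    )
    state <- upd$state
    opt <- upd$opt

    fw2 <- encode_forward(X, P, state)
    monitor <- if (has_val) {
      vs <- rowSums(fw2$H[va_idx[, 1], , drop = FALSE] *
        fw2$H[va_idx[, 2], , drop = FALSE])
      bce_loss(vs, va_lab)
    } else {
      ts <- rowSums(fw2$H[tr_idx[, 1], , drop = FALSE] *
        fw2$H[tr_idx[, 2], , drop = FALSE])
      bce_loss(ts, tr_lab)
    }
    hist_train[epoch] <- train_loss
    hist_val[epoch] <- monitor
    if (monitor < best_loss) {
      best_loss <- monitor
      best_state <- state
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= train_cfg$patience) break
    }
  }
  n_run <- epoch

  H <- encode(X, P, best_state)
  structure(
    list(
      state = best_state,
      H = H,
      P = P,
      graph_nodes = graph$nodes$name,
      history = tibble::tibble(
        epoch = seq_len(n_run),
        train_loss = hist_train[seq_len(n_run)],
        val_loss = hist_val[seq_len(n_run)]
      ),
      best_epoch = best_epoch,
      best_val_loss = best_loss,
      model_config = model_config,
      train_config = train_cfg
    ),
    class = "collab_gnn"
  )
}

#' @export
print.collab_gnn <- function(x, ...) {
  cat(
    "<collab_gnn> ", x$model_config$encoder, " encoder, ",
    x$model_config$n_layers, " layer(s), hidden dim ",
    x$model_config$hidden_dim, "\n",
    "  trained ", nrow(x$history), " epoch(s); best epoch ", x$best_epoch,
    " (monitored loss ", format(x$best_val_loss, digits = 5), ")\n",
    sep = ""
  )
  invisible(x)
}
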