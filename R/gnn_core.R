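# Graph encoders (two-layer GCN / GraphSAGE-mean) and dot-product scoring.
# Dense base-R linear algebra throughout: collaboration graphs at this
# scale are a few hundred nodes, so sparsity buys nothing.

#' Encoder configuration
#'
#' @param encoder `"gcn"` (symmetric-normalized propagation with self-loops)
#'   or `"sage"` (GraphSAGE with mean neighborhood aggregation).
#' @param n_layers Number of layers (>= 1, default 2).
#' @param hidden_dim Width of every hidden/output layer (default 128).
#' @param use_edge_weights If `TRUE`, collaboration counts enter the
#'   propagation matrix; if `FALSE` the binarized adjacency is used.
#' @param fuse_edge_attr If `TRUE` (and edge weights are in use), each
#'   edge's weight is multiplied by its normalized intervention attribute
#'   before adjacency normalization, letting the edge attribute modulate
#'   message passing.
#' @return A `model_config` list.
#' @export
model_config <- function(encoder = c("gcn", "sage"), n_layers = 2L,
                         hidden_dim = 128L, use_edge_weights = TRUE,
                         fuse_edge_attr = TRUE) {
  encoder <- match.arg(encoder)
  stopifnot(n_layers >= 1, hidden_dim >= 1)
  structure(
    list(
      encoder = encoder, n_layers = as.integer(n_layers),
      hidden_dim = as.integer(hidden_dim),
      use_edge_weights = isTRUE(use_edge_weights),
      fuse_edge_attr = isTRUE(fuse_edge_attr)
    ),
    class = "model_config"
  )
}

check_square_symmetric <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("Adjacency must be a square matrix", call. = FALSE)
  }
  if (nrow(A) > 0 && max(abs(A - t(A))) > 1e-12) {
    stop("Adjacency must be symmetric", call. = FALSE)
  }
  if (nrow(A) > 0 && any(diag(A) != 0)) {
    stop("Adjacency must have a zero diagonal", call. = FALSE)
  }
  invisible(A)
}

#' Symmetric-normalized adjacency with self-loops
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)` where `D` is the diagonal of row
#' sums of `A + I` — the standard GCN propagation matrix. With
#' `use_edge_weights = FALSE` the input is binarized first, so rescaling
#' all weights leaves the result unchanged.
#'
#' @param A Symmetric adjacency matrix with zero diagonal.
#' @param use_edge_weights Keep weighted entries (default) or binarize.
#' @return The normalized propagation matrix.
#' @export
normalize_adjacency <- function(A, use_edge_weights = TRUE) {
  check_square_symmetric(A)
  if (!use_edge_weights) A <- (A != 0) * 1
  n <- nrow(A)
  Ahat <- A + diag(n)
  dinv <- 1 / sqrt(rowSums(Ahat))
  Ahat * (dinv %o% dinv)
}

# Row-normalized adjacency without self-loops: the mean-aggregation
# operator for GraphSAGE. Isolated nodes aggregate the zero vector.
neighbor_mean_matrix <- function(A, use_edge_weights = TRUE) {
  check_square_symmetric(A)
  if (!use_edge_weights) A <- (A != 0) * 1
  rs <- rowSums(A)
  rs[rs == 0] <- 1
  A / rs
}

propagation_matrix <- function(A, config) {
  switch(config$encoder,
    gcn = normalize_adjacency(A, config$use_edge_weights),
    sage = neighbor_mean_matrix(A, config$use_edge_weights)
  )
}

glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(runif(fin * fout, -lim, lim), fin, fout)
}

#' Initialize encoder weights
#'
#' Glorot-uniform initialization, seeded for determinism. GCN layers carry
#' one weight matrix each; GraphSAGE layers carry separate self and
#' neighbor matrices. Widths chain input -> hidden -> ... -> hidden. No
#' bias terms are used.
#'
#' @param input_dim Width of the node feature matrix.
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return A `model_state` list of per-layer weight matrices.
#' @export
init_model_state <- function(input_dim, config = model_config(), seed = 1L) {
  dims <- c(input_dim, rep(config$hidden_dim, config$n_layers))
  layers <- withr::with_seed(seed, lapply(seq_len(config$n_layers), function(l) {
    if (config$encoder == "gcn") {
      list(W = glorot(dims[l], dims[l + 1]))
    } else {
      list(
        W_self = glorot(dims[l], dims[l + 1]),
        W_nbr = glorot(dims[l], dims[l + 1])
      )
    }
  }))
  structure(
    list(layers = layers, config = config, input_dim = as.integer(input_dim), seed = seed),
    class = "model_state"
  )
}

relu <- function(x) pmax(x, 0)

# Forward pass keeping pre-activations and hidden states for backprop.
encode_forward <- function(X, P, state, config = state$config) {
  L <- config$n_layers
  Hs <- vector("list", L + 1)
  Zs <- vector("list", L)
  Hs[[1]] <- X
  for (l in seq_len(L)) {
    lay <- state$layers[[l]]
    Z <- if (config$encoder == "gcn") {
      P %*% Hs[[l]] %*% lay$W
    } else {
      Hs[[l]] %*% lay$W_self + (P %*% Hs[[l]]) %*% lay$W_nbr
    }
    Zs[[l]] <- Z
    Hs[[l + 1]] <- if (l < L) relu(Z) else Z
  }
  list(H = Hs[[L + 1]], Hs = Hs, Zs = Zs)
}

#' Encode node features into embeddings
#'
#' Runs the configured encoder. GCN layers compute
#' `H' = act(P H W)` with `P` the symmetric-normalized adjacency
#' ([normalize_adjacency()]); GraphSAGE layers compute
#' `H' = act(H W_self + mean_nbr(H) W_nbr)`. The activation is a rectifier
#' between layers and the identity at the output.
#'
#' @param X Node feature matrix (rows aligned to the propagation matrix).
#' @param P Propagation matrix for the configured encoder (normalized
#'   adjacency for GCN, row-normalized neighbor-mean matrix for SAGE).
#' @param state A [init_model_state()] (possibly trained).
#' @param config A [model_config()]; defaults to the state's config.
#' @return Embedding matrix `H`, one row per node, `hidden_dim` columns.
#' @export
encode <- function(X, P, state, config = state$config) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != nrow(P)) {
    stop("Feature matrix and propagation matrix disagree on node count", call. = FALSE)
  }
  if (ncol(X) != state$input_dim) {
    stop(
      "Feature width ", ncol(X), " does not match model input width ",
      state$input_dim,
      call. = FALSE
    )
  }
  H <- encode_forward(X, P, state, config)$H
  rownames(H) <- rownames(X)
  H
}

#' Collaboration score of one candidate pair
#'
#' The inner product of the two embeddings: an unnormalized log-odds of a
#' collaboration link. Symmetric in its arguments.
#'
#' @param h_u,h_i Embedding vectors of equal length.
#' @return A single numeric score.
#' @export
dot_score <- function(h_u, h_i) {
  if (length(h_u) != length(h_i)) {
    stop("Embedding lengths differ", call. = FALSE)
  }
  sum(h_u * h_i)
}

#' Score a list of node pairs
#'
#' @param H Embedding matrix (rownames = node names).
#' @param edges Either a two-column integer matrix of row indices into `H`,
#'   or a tibble/data frame with character columns `u`, `v` of node names.
#' @return Numeric vector of dot-product scores, in input order.
#' @export
score_edges <- function(H, edges) {
  idx <- edges_to_index(edges, H)
  if (nrow(idx) == 0) {
    return(numeric())
  }
  unname(rowSums(H[idx[, 1], , drop = FALSE] * H[idx[, 2], , drop = FALSE]))
}

edges_to_index <- function(edges, H) {
  if (is.data.frame(edges)) {
    i <- match(edges$u, rownames(H))
    j <- match(edges$v, rownames(H))
    if (anyNA(i) || anyNA(j)) {
      stop("Edge endpoint not present in embedding matrix", call. = FALSE)
    }
    return(cbind(i, j))
  }
  edges <- as.matrix(edges)
  if (nrow(edges) > 0 &&
    (min(edges) < 1 || max(edges) > nrow(H))) {
    stop("Edge index out of range", call. = FALSE)
  }
  storage.mode(edges) <- "integer"
  edges
}

#' Save / load a model state
#'
#' Serializes the per-layer weight matrices together with the configuration
#' as a single JSON archive. Doubles are written in full hexadecimal
#' precision so the round-trip is bit-exact.
#'
#' @param state A `model_state`.
#' @param path File path.
#' @return `path` (save) or the restored `model_state` (load).
#' @export
save_model_state <- function(state, path) {
  ser_mat <- function(M) list(
    dim = dim(M),
    data = sprintf("%a", as.vector(M))
  )
  payload <- list(
    config = unclass(state$config),
    input_dim = state$input_dim,
    seed = state$seed,
    layers = lapply(state$layers, function(lay) lapply(lay, ser_mat))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model_state
#' @export
load_model_state <- function(path) {
  payload <- jsonlite::read_json(
    path,
    simplifyVector = TRUE, simplifyDataFrame = FALSE, simplifyMatrix = FALSE
  )
  cfg <- payload$config
  config <- model_config(
    encoder = cfg$encoder, n_layers = cfg$n_layers,
    hidden_dim = cfg$hidden_dim, use_edge_weights = cfg$use_edge_weights,
    fuse_edge_attr = cfg$fuse_edge_attr
  )
  de_mat <- function(m) {
    vals <- vapply(m$data, function(s) strtod_hex(s), numeric(1))
    matrix(vals, m$dim[[1]], m$dim[[2]])
  }
  layers <- lapply(payload$layers, function(lay) lapply(lay, de_mat))
  structure(
    list(
      layers = layers, config = config,
      input_dim = as.integer(payload$input_dim), seed = payload$seed
    ),
    class = "model_state"
  )
}

strtod_hex <- function(s) {
  # %a hex float round-trips exactly through scan()
  scan(text = s, what = double(), quiet = TRUE)
}
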