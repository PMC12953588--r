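# Node attribute fusion: trial activity, country profile, intervention
# profile -> fixed-width feature matrix via a pluggable text embedder.

#' Deterministic feature-hashing text encoder
#'
#' A local, offline embedding provider: the text is lower-cased and split on
#' non-alphanumeric characters, each token is hashed into one of `dim`
#' buckets with a +/-1 sign, and the resulting vector is L2-normalized.
#' The same text always maps to the same vector for a fixed `(dim, seed)`;
#' the empty string maps to the zero vector. External embedding services
#' can be swapped in through the same provider contract
#' (see [embedding_provider()]).
#'
#' @param dim Embedding width (>= 1).
#' @param seed Integer salt entering every hash, so different seeds give
#'   independent encoders.
#' @return An `embedding_provider`.
#' @export
default_text_encoder <- function(dim, seed = 1L) {
  if (!is.numeric(dim) || length(dim) != 1 || dim < 1) {
    stop("'dim' must be a single integer >= 1", call. = FALSE)
  }
  dim <- as.integer(dim)
  cache <- new.env(parent = emptyenv())
  embed_one <- function(text) {
    key <- paste0("k", text)
    hit <- cache[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    v <- numeric(dim)
    tokens <- stringi::stri_split_regex(tolower(text), "[^a-z0-9]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    for (tok in tokens) {
      h1 <- strtoi(substr(
        digest::digest(paste0(seed, "\x1f", tok), algo = "xxhash32", serialize = FALSE),
        1, 7
      ), 16L)
      h2 <- strtoi(substr(
        digest::digest(paste0(seed, "\x1e", tok), algo = "xxhash32", serialize = FALSE),
        1, 7
      ), 16L)
      bucket <- h1 %% dim + 1L
      sign <- if (h2 %% 2L == 0L) 1 else -1
      v[bucket] <- v[bucket] + sign
    }
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    cache[[key]] <- v
    v
  }
  embedding_provider(
    name = sprintf("hash%d-seed%d", dim, seed),
    dim = dim,
    embed = function(texts) {
      out <- t(vapply(as.character(texts), embed_one, numeric(dim)))
      rownames(out) <- NULL
      out
    }
  )
}

#' Construct an embedding provider
#'
#' The provider contract used by [fuse_node_features()]: `embed` maps a
#' character vector of texts to a numeric matrix with one row per text and
#' `dim` columns, deterministically for a fixed provider configuration, and
#' must return finite values.
#'
#' @param name Provider label.
#' @param dim Output width.
#' @param embed Function `character -> matrix(length(texts), dim)`.
#' @return An object of class `embedding_provider`.
#' @export
embedding_provider <- function(name, dim, embed) {
  stopifnot(is.function(embed), dim >= 1)
  structure(
    list(name = name, dim = as.integer(dim), embed = embed),
    class = "embedding_provider"
  )
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat("<embedding_provider> ", x$name, " (dim ", x$dim, ")\n", sep = "")
  invisible(x)
}

dominant_key <- function(tab) {
  if (length(tab) == 0) {
    return("")
  }
  # mode; ties broken lexicographically (counts table is already radix-sorted)
  names(tab)[which.max(tab)]
}

#' Fuse node attributes into the model's feature matrix
#'
#' Per node, concatenates: `log(1 + trial_count)`; the provider embedding of
#' the node's dominant country (mode over its trials, ties lexicographic);
#' its normalized intervention-category histogram (fixed category order over
#' the whole graph, rows sum to 1 or are all zero); and the provider
#' embedding of the dominant intervention category. If the concatenation
#' width differs from `out_dim`, a seeded random Gaussian projection maps it
#' to `out_dim`, so the encoder input width is under user control while the
#' histograms retain full attribute information upstream of the projection.
#'
#' @param graph A `collab_graph`.
#' @param provider An [embedding_provider()]; default a 32-dimensional
#'   feature-hashing encoder.
#' @param out_dim Target feature width, or `NULL` to keep the raw
#'   concatenation width.
#' @param seed Seed for the projection matrix.
#' @return Numeric matrix, one row per node in the graph's stable node
#'   order (rownames = node names).
#' @export
fuse_node_features <- function(graph, provider = default_text_encoder(32),
                               out_dim = 128L, seed = 1L) {
  n <- nrow(graph$nodes)
  categories <- sort_c(unique(unlist(
    lapply(graph$nodes$intervention_counts, names),
    use.names = FALSE
  )))
  if (n == 0) {
    width <- out_dim %||% (1L + 2L * provider$dim + length(categories))
    return(matrix(numeric(), 0, width))
  }

  hist_mat <- matrix(0, n, length(categories), dimnames = list(NULL, categories))
  for (i in seq_len(n)) {
    tab <- graph$nodes$intervention_counts[[i]]
    if (length(tab) > 0) {
      hist_mat[i, names(tab)] <- tab / sum(tab)
    }
  }

  dom_country <- vapply(graph$nodes$country_counts, dominant_key, "")
  dom_cat <- vapply(graph$nodes$intervention_counts, dominant_key, "")

  X <- cbind(
    log1p(graph$nodes$trial_count),
    provider$embed(dom_country),
    hist_mat,
    provider$embed(dom_cat)
  )
  if (any(!is.finite(X))) {
    stop("Embedding provider returned non-finite values", call. = FALSE)
  }

  if (!is.null(out_dim) && ncol(X) != out_dim) {
    P <- withr::with_seed(
      seed,
      matrix(rnorm(ncol(X) * out_dim), ncol(X), out_dim) / sqrt(ncol(X))
    )
    X <- X %*% P
  }
  rownames(X) <- graph$nodes$name
  colnames(X) <- NULL
  X
}

#' Structure-only node features (attribute-free ablation)
#'
#' Encodes each node by its graph role alone: an intercept, `log(1 +
#' trial_count)` and `log(1 + degree)`. Used as the attribute-free baseline
#' against which the fused features are compared.
#'
#' @param graph A `collab_graph`.
#' @return Numeric matrix with one row per node (rownames = node names).
#' @export
structure_node_features <- function(graph) {
  deg <- node_degrees(graph)
  X <- cbind(1, log1p(graph$nodes$trial_count), log1p(as.numeric(deg)))
  rownames(X) <- graph$nodes$name
  colnames(X) <- NULL
  X
}

#' Persist a feature matrix for inspection
#'
#' @param X Feature matrix with node rownames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  tab <- tibble::as_tibble(as.data.frame(X), .name_repair = "minimal")
  names(tab) <- paste0("f", seq_len(ncol(tab)))
  tab <- dplyr::bind_cols(tibble::tibble(name = rownames(X)), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
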