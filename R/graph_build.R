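# Cumulative weighted undirected collaboration graph.

new_collab_graph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "collab_graph")
}

#' Build the co-collaboration graph from trial records
#'
#' Every trial contributes a clique over its affiliations: each unordered
#' pair gains +1 to its edge weight (`collab_count`), and every listed
#' affiliation gains +1 to its node weight (`trial_count`). Country and
#' intervention-category counts are accumulated per node from the trials it
#' participates in; per edge, `intervention_raw` counts the co-trials that
#' list at least one intervention. Trials with a single affiliation yield
#' isolated nodes; no self-loops are ever created. When the graph has at
#' least one edge, `intervention_norm` is filled by
#' [normalize_edge_interventions()].
#'
#' @param records A canonicalized trial-record tibble (see [canonicalize()]).
#' @return A `collab_graph`: a list with
#'   * `nodes`: tibble (`name`, `trial_count`, `country_counts`,
#'     `intervention_counts`), rows in stable radix-sorted name order, which
#'     defines the matrix row order everywhere downstream;
#'   * `edges`: tibble (`u`, `v`, `collab_count`, `intervention_raw`,
#'     `intervention_norm`) with `u < v` in the same order.
#' @export
build_graph <- function(records) {
  n <- nrow(records)
  affs <- lapply(records$affiliations, function(a) sort_c(unique(a)))

  node_names <- sort_c(unique(unlist(affs, use.names = FALSE)))

  trial_count <- integer(length(node_names))
  names(trial_count) <- node_names
  country_counts <- stats::setNames(
    replicate(length(node_names), integer(), simplify = FALSE), node_names
  )
  intervention_counts <- country_counts

  edge_u <- vector("list", n)
  edge_v <- vector("list", n)
  edge_iv <- vector("list", n)
  for (i in seq_len(n)) {
    a <- affs[[i]]
    trial_count[a] <- trial_count[a] + 1L
    ctry <- records$countries[[i]]
    cats <- records$interventions[[i]]$category
    for (node in a) {
      if (length(ctry)) {
        country_counts[[node]] <- add_counts(country_counts[[node]], ctry)
      }
      if (length(cats)) {
        intervention_counts[[node]] <- add_counts(intervention_counts[[node]], cats)
      }
    }
    if (length(a) >= 2) {
      pr <- combn(a, 2) # columns already canonical: a is radix-sorted
      edge_u[[i]] <- pr[1, ]
      edge_v[[i]] <- pr[2, ]
      edge_iv[[i]] <- rep(length(cats) > 0, ncol(pr))
    }
  }

  pair_tab <- tibble::tibble(
    u = unlist(edge_u) %||% character(),
    v = unlist(edge_v) %||% character(),
    has_iv = unlist(edge_iv) %||% logical()
  )
  edges <- pair_tab |>
    dplyr::group_by(.data$u, .data$v) |>
    dplyr::summarise(
      collab_count = dplyr::n(),
      intervention_raw = sum(.data$has_iv),
      .groups = "drop"
    ) |>
    dplyr::mutate(intervention_norm = NA_real_)
  edges <- edges[order_c(edges$u, edges$v), ]

  nodes <- tibble::tibble(
    name = node_names,
    trial_count = as.integer(unname(trial_count)),
    country_counts = lapply(country_counts, sort_counts),
    intervention_counts = lapply(intervention_counts, sort_counts)
  )

  g <- new_collab_graph(nodes, edges)
  if (nrow(edges) > 0) g <- normalize_edge_interventions(g)
  g
}

add_counts <- function(tab, keys) {
  for (k in keys) {
    cur <- tab[k]
    tab[k] <- if (is.na(cur)) 1L else cur + 1L
  }
  tab
}

sort_counts <- function(tab) {
  if (length(tab) == 0) {
    return(stats::setNames(integer(), character()))
  }
  tab[sort_c(names(tab))]
}

#' @export
print.collab_graph <- function(x, ...) {
  cat(
    "<collab_graph> ", nrow(x$nodes), " affiliations, ",
    nrow(x$edges), " collaboration edges\n",
    sep = ""
  )
  if (nrow(x$nodes) > 0) {
    cat(
      " total trials per node: sum ", sum(x$nodes$trial_count),
      ", max ", max(x$nodes$trial_count), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Disease-centric subgraph
#'
#' Filters the records with [filter_by_condition()] and builds the graph of
#' the matching trials only, so node and edge weights reflect the selected
#' disease area alone.
#'
#' @inheritParams build_graph
#' @param keywords Condition keywords (case-insensitive substrings matched
#'   against title and conditions).
#' @return A `collab_graph`.
#' @export
condition_subgraph <- function(records, keywords) {
  build_graph(filter_by_condition(records, keywords))
}

#' Min-max normalize the per-edge intervention counts
#'
#' Rescales `intervention_raw` across all edges to `[0, 1]`:
#' `(raw - min) / (max - min)`. When all raw counts coincide (including the
#' single-edge case) every edge gets 1.0, so a uniform attribute does not
#' erase edge information. An edgeless graph is returned unchanged with a
#' warning.
#'
#' @param graph A `collab_graph`.
#' @return The graph with `intervention_norm` filled in.
#' @export
normalize_edge_interventions <- function(graph) {
  raw <- graph$edges$intervention_raw
  if (length(raw) == 0) {
    warning("Graph has no edges; nothing to normalize", call. = FALSE)
    return(graph)
  }
  rng <- range(raw)
  graph$edges$intervention_norm <- if (rng[1] == rng[2]) {
    rep(1.0, length(raw))
  } else {
    (raw - rng[1]) / (rng[2] - rng[1])
  }
  graph
}

#' Adjacency matrix of a collaboration graph
#'
#' @param graph A `collab_graph`.
#' @param weighted If `TRUE` entries are `collab_count`; otherwise 1/0.
#' @return A symmetric numeric matrix with zero diagonal, rows and columns
#'   in the graph's stable node order (dimnames set to node names).
#' @export
adjacency <- function(graph, weighted = TRUE) {
  nm <- graph$nodes$name
  A <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  if (nrow(graph$edges) > 0) {
    i <- match(graph$edges$u, nm)
    j <- match(graph$edges$v, nm)
    w <- if (weighted) graph$edges$collab_count else 1
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  A
}

# Adjacency restricted to a set of edges (tibble u, v), with optional
# intervention fusion: weight = collab_count * intervention_norm. Used to
# build the message-passing graph from training edges only.
restricted_adjacency <- function(graph, keep_pairs = NULL,
                                 use_edge_weights = TRUE,
                                 fuse_edge_attr = FALSE) {
  nm <- graph$nodes$name
  edges <- graph$edges
  if (!is.null(keep_pairs)) {
    edges <- edges[pair_keys(edges) %in% pair_keys(keep_pairs), ]
  }
  A <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  if (nrow(edges) > 0) {
    w <- if (use_edge_weights) as.numeric(edges$collab_count) else rep(1, nrow(edges))
    if (fuse_edge_attr && use_edge_weights && !anyNA(edges$intervention_norm)) {
      w <- w * edges$intervention_norm
    }
    i <- match(edges$u, nm)
    j <- match(edges$v, nm)
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  A
}

node_degrees <- function(graph) {
  deg <- stats::setNames(integer(nrow(graph$nodes)), graph$nodes$name)
  if (nrow(graph$edges) > 0) {
    t1 <- table(graph$edges$u)
    t2 <- table(graph$edges$v)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

#' Write a graph as node and edge tables
#'
#' Emits `nodes.tsv` (name, trial_count, top country, intervention counts as
#' a JSON cell) and `edges.tsv` (u, v, collab_count, intervention_norm)
#' under `dir`.
#'
#' @param graph A `collab_graph`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_graph_tables <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  top_or_na <- function(tab) {
    if (length(tab) == 0) NA_character_ else names(tab)[which.max(tab)]
  }
  nodes <- tibble::tibble(
    name = graph$nodes$name,
    trial_count = graph$nodes$trial_count,
    top_country = vapply(graph$nodes$country_counts, top_or_na, ""),
    intervention_counts = vapply(
      graph$nodes$intervention_counts,
      function(tab) as.character(jsonlite::toJSON(as.list(tab), auto_unbox = TRUE)),
      ""
    )
  )
  readr::write_tsv(nodes, file.path(dir, "nodes.tsv"), progress = FALSE)
  readr::write_tsv(
    graph$edges[, c("u", "v", "collab_count", "intervention_norm")],
    file.path(dir, "edges.tsv"),
    progress = FALSE
  )
  invisible(dir)
}

#' Convert to an igraph object
#'
#' Convenience export for external layout/visualization tools; requires the
#' igraph package.
#'
#' @param graph A `collab_graph`.
#' @return An igraph undirected weighted graph.
#' @export
as_igraph <- function(graph) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("Package 'igraph' is required for as_igraph()", call. = FALSE)
  }
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("u", "v", "collab_count", "intervention_norm")],
    directed = FALSE,
    vertices = graph$nodes[, c("name", "trial_count")]
  )
  igraph::E(ig)$weight <- graph$edges$collab_count
  ig
}
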