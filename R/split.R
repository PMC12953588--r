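# Train/validation/test edge splits and negative sampling.

#' Construct an edge split
#'
#' Container for the positive and negative edge sets of a link-prediction
#' experiment. All six members are pair tibbles with character columns
#' `u`, `v`, stored canonically (`u < v` in radix order).
#'
#' @param train_pos,train_neg,val_pos,val_neg,test_pos,test_neg Pair
#'   tibbles (default empty).
#' @return An `edge_split` object.
#' @export
edge_split <- function(train_pos = empty_pairs(), train_neg = empty_pairs(),
                       val_pos = empty_pairs(), val_neg = empty_pairs(),
                       test_pos = empty_pairs(), test_neg = empty_pairs()) {
  as_pairs <- function(p) canonical_pairs(p$u, p$v)
  structure(
    list(
      train_pos = as_pairs(train_pos), train_neg = as_pairs(train_neg),
      val_pos = as_pairs(val_pos), val_neg = as_pairs(val_neg),
      test_pos = as_pairs(test_pos), test_neg = as_pairs(test_neg)
    ),
    class = "edge_split"
  )
}

#' @export
print.edge_split <- function(x, ...) {
  sizes <- vapply(x, nrow, integer(1))
  cat("<edge_split>\n")
  for (nm in names(sizes)) cat("  ", nm, ": ", sizes[[nm]], " pairs\n", sep = "")
  invisible(x)
}

#' Validate the disjointness and balance invariants of a split
#'
#' Checks that no pair appears in two roles, that every negative set is
#' disjoint from every positive set, and (when `require_negatives`) that
#' each negative set matches its positive set 1:1 in size.
#'
#' @param split An `edge_split`.
#' @param require_negatives Enforce the 1:1 negative contract (default
#'   `TRUE`; use `FALSE` for splits whose negatives are filled later).
#' @return `split`, invisibly; errors describe the first violated invariant.
#' @export
validate_edge_split <- function(split, require_negatives = TRUE) {
  keys <- lapply(split, pair_keys)
  nms <- names(keys)
  for (a in seq_along(keys)) {
    if (anyDuplicated(keys[[a]])) {
      stop("Duplicate pairs within ", nms[[a]], call. = FALSE)
    }
    for (b in seq_along(keys)) {
      if (b <= a) next
      if (length(intersect(keys[[a]], keys[[b]])) > 0) {
        stop("Pair appears in both ", nms[[a]], " and ", nms[[b]], call. = FALSE)
      }
    }
  }
  if (require_negatives) {
    for (role in c("train", "val", "test")) {
      np <- nrow(split[[paste0(role, "_pos")]])
      nn <- nrow(split[[paste0(role, "_neg")]])
      if (np != nn) {
        stop(
          "Negative set for '", role, "' is not 1:1 with positives (",
          nn, " vs ", np, ")",
          call. = FALSE
        )
      }
    }
  }
  invisible(split)
}

# Per-pair support years across all trials.
pair_years <- function(records) {
  keep <- !is.na(records$year)
  rows <- which(keep & vapply(records$affiliations, length, integer(1)) >= 2)
  if (length(rows) == 0) {
    return(tibble::tibble(u = character(), v = character(), year = integer()))
  }
  pieces <- lapply(rows, function(i) {
    a <- sort_c(unique(records$affiliations[[i]]))
    pr <- combn(a, 2)
    tibble::tibble(u = pr[1, ], v = pr[2, ], year = records$year[[i]])
  })
  dplyr::bind_rows(pieces)
}

#' Temporal edge split
#'
#' Training positives are pairs supported by any co-trial registered in or
#' before `cutoff_year`; test positives are pairs first appearing exactly
#' in `cutoff_year + 1`; pairs first appearing later are ignored. Records
#' without a year are dropped (they cannot be placed on the timeline).
#' Negative sets are left empty — fill them with [sample_negatives()].
#'
#' @param records Trial records carrying registration years.
#' @param cutoff_year Last training year.
#' @return An `edge_split` with positives only.
#' @export
temporal_split <- function(records, cutoff_year) {
  if (all(is.na(records$year))) {
    stop(
      "No record carries a registration year; use random_split_with_isolated()",
      call. = FALSE
    )
  }
  py <- pair_years(records)
  first <- py |>
    dplyr::group_by(.data$u, .data$v) |>
    dplyr::summarise(first_year = min(.data$year), .groups = "drop")
  edge_split(
    train_pos = first[first$first_year <= cutoff_year, c("u", "v")],
    test_pos = first[first$first_year == cutoff_year + 1, c("u", "v")]
  )
}

#' Random edge split keeping every node covered in training
#'
#' Shuffles the graph's edges under the seed and assigns
#' `round(test_fraction * n_edges)` of them to the test set, except that an
#' edge is never tested if that would leave one of its endpoints with no
#' training edge (such edges are forced into training, so isolated and
#' leaf-attached structure always trains). Deterministic per seed.
#'
#' @param graph A `collab_graph`.
#' @param test_fraction Fraction of edges targeted for testing, in (0, 1).
#' @param seed Integer seed.
#' @return An `edge_split` with positives only.
#' @export
random_split_with_isolated <- function(graph, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  edges <- graph$edges
  if (nrow(edges) == 0) {
    stop("Graph has no edges to split", call. = FALSE)
  }
  n_target <- round(test_fraction * nrow(edges))
  deg <- node_degrees(graph)
  ord <- withr::with_seed(seed, sample.int(nrow(edges)))
  is_test <- logical(nrow(edges))
  picked <- 0L
  for (k in ord) {
    if (picked >= n_target) break
    u <- edges$u[[k]]
    v <- edges$v[[k]]
    if (deg[[u]] > 1 && deg[[v]] > 1) {
      is_test[[k]] <- TRUE
      deg[[u]] <- deg[[u]] - 1L
      deg[[v]] <- deg[[v]] - 1L
      picked <- picked + 1L
    }
  }
  edge_split(
    train_pos = edges[!is_test, c("u", "v")],
    test_pos = edges[is_test, c("u", "v")]
  )
}

#' Sample negative (non-collaborating) pairs
#'
#' Draws uniformly without replacement from the unordered node pairs that
#' are not edges of `graph` and not in `forbidden`. Deterministic per seed.
#'
#' @param graph A `collab_graph` defining the node set and adjacency.
#' @param positives_to_match A pair tibble whose row count sets the sample
#'   size (the 1:1 contract), or a single integer.
#' @param forbidden Pair tibble of additional pairs to exclude (e.g. all
#'   positives of every role and previously drawn negatives).
#' @param seed Integer seed.
#' @return A pair tibble with as many rows as requested.
#' @export
sample_negatives <- function(graph, positives_to_match,
                             forbidden = empty_pairs(), seed = 1L) {
  n <- if (is.data.frame(positives_to_match)) {
    nrow(positives_to_match)
  } else {
    as.integer(positives_to_match)
  }
  if (n == 0) {
    return(empty_pairs())
  }
  pool <- non_edge_pool(graph, forbidden)
  if (nrow(pool) < n) {
    stop(
      "Cannot sample ", n, " negative pairs: only ", nrow(pool),
      " non-connected pairs available",
      call. = FALSE
    )
  }
  rows <- withr::with_seed(seed, sample.int(nrow(pool), n))
  pool[rows, ]
}

non_edge_pool <- function(graph, forbidden = empty_pairs()) {
  nm <- graph$nodes$name
  if (length(nm) < 2) {
    return(empty_pairs())
  }
  pr <- combn(nm, 2) # nm is radix-sorted, so pairs are canonical
  pool <- tibble::tibble(u = pr[1, ], v = pr[2, ])
  excl <- c(pair_keys(graph$edges), pair_keys(forbidden))
  pool[!(pair_keys(pool) %in% excl), ]
}
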