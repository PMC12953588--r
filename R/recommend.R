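# Ranked top-N collaboration recommendations for a target affiliation.

#' Recommend collaboration partners for an affiliation
#'
#' Scores every other node against the target by the dot product of their
#' trained embeddings and returns the top `n`, sorted by score descending
#' with lexicographic tie-break. With `include_existing = FALSE` only
#' non-partners (nodes not adjacent to the target in the graph) are
#' candidates, i.e. genuinely new collaborations.
#'
#' @param graph The `collab_graph` the model was trained on.
#' @param H Embedding matrix from a trained fit (e.g. `fit$H`), rownames =
#'   node names.
#' @param target Affiliation name (must be a node of `graph`).
#' @param n Number of recommendations (>= 1).
#' @param include_existing Keep current partners among the candidates
#'   (default `TRUE`).
#' @return A `collab_ranking` tibble with columns `rank`, `candidate`,
#'   `score` (raw dot product), `probability` (sigmoid of the score) and
#'   `existing_partner`.
#' @export
recommend_top_n <- function(graph, H, target, n = 10L,
                            include_existing = TRUE) {
  stopifnot(n >= 1)
  nm <- graph$nodes$name
  if (!(target %in% nm)) {
    near <- agrep(target, nm, max.distance = 0.3, value = TRUE)
    stop(
      "Unknown affiliation '", target, "'",
      if (length(near) > 0) {
        paste0("; nearest matches: ", paste(head(near, 5), collapse = ", "))
      } else {
        ""
      },
      call. = FALSE
    )
  }
  partners <- unique(c(
    graph$edges$v[graph$edges$u == target],
    graph$edges$u[graph$edges$v == target]
  ))
  cands <- setdiff(nm, target)
  if (!include_existing) cands <- setdiff(cands, partners)
  scores <- score_edges(
    H, tibble::tibble(u = rep(target, length(cands)), v = cands)
  )
  ord <- order(-scores, cands, method = "radix")
  cands <- cands[ord]
  scores <- scores[ord]
  keep <- seq_len(min(n, length(cands)))
  out <- tibble::tibble(
    rank = keep,
    candidate = cands[keep],
    score = scores[keep],
    probability = plogis(scores[keep]),
    existing_partner = cands[keep] %in% partners
  )
  structure(out, class = c("collab_ranking", class(out)), target = target)
}

#' @export
print.collab_ranking <- function(x, ...) {
  cat("<collab_ranking> target: ", attr(x, "target"), "\n", sep = "")
  NextMethod()
}

#' Write a ranking as TSV
#'
#' @param ranking A `collab_ranking`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  readr::write_tsv(as.data.frame(ranking), path, progress = FALSE)
  invisible(path)
}
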