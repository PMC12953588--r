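# Evaluation metrics: ROC AUC (rank form), F1, Accuracy@K.

#' ROC AUC from positive and negative scores
#'
#' The probability that a uniformly drawn positive outranks a uniformly
#' drawn negative, with ties counted 1/2 — the rank-statistic form of the
#' area under the ROC curve.
#'
#' @param pos_scores,neg_scores Non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0) {
    stop("Both score vectors must be non-empty", call. = FALSE)
  }
  np <- length(pos_scores)
  nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' F1 score of thresholded link probabilities
#'
#' Predictions are `sigmoid(score) >= threshold`; F1 is the harmonic mean
#' of precision and recall, defined as 0 when precision + recall is 0 (in
#' particular when nothing is predicted positive).
#'
#' @param scores Numeric scores (logits).
#' @param labels 0/1 (or logical) true labels, same length.
#' @param threshold Probability threshold (default 0.5, i.e. score >= 0).
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("'scores' and 'labels' must have equal length", call. = FALSE)
  }
  pred <- plogis(scores) >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (tp == 0 && (fp > 0 || fn > 0)) {
    return(0)
  }
  if (tp + fp == 0 || tp + fn == 0) {
    return(0)
  }
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  if (precision + recall == 0) {
    return(0)
  }
  2 * precision * recall / (precision + recall)
}

#' Accuracy@K over per-user rankings
#'
#' For each user `i` with relevant set `Rel_i` and ranked recommendations
#' `Rec_i(k)` (the first `k` candidates), computes either the literal mean
#' hit count `(1/N) * sum |Rel_i intersect Rec_i(k)|`, or the normalized
#' hit ratio with denominator `min(k, |Rel_i|)`, which is bounded by 1.
#' Users with an empty relevant set are skipped (with a warning) and do not
#' count toward `N`.
#'
#' @param rankings Named list: user -> character vector of candidates in
#'   descending score order.
#' @param relevants Named list over the same users: user -> character
#'   vector of relevant items.
#' @param k Cutoff (>= 1).
#' @param mode `"normalized"` (default) or `"literal"`.
#' @return A single numeric value.
#' @export
accuracy_at_k <- function(rankings, relevants, k,
                          mode = c("normalized", "literal")) {
  mode <- match.arg(mode)
  stopifnot(k >= 1)
  if (!setequal(names(rankings), names(relevants))) {
    stop("'rankings' and 'relevants' must cover the same users", call. = FALSE)
  }
  users <- names(rankings)
  n_rel <- vapply(relevants[users], length, integer(1))
  if (any(n_rel == 0)) {
    warning(
      sum(n_rel == 0), " user(s) with no relevant items skipped",
      call. = FALSE
    )
    users <- users[n_rel > 0]
  }
  if (length(users) == 0) {
    return(NA_real_)
  }
  per_user <- vapply(users, function(u) {
    hits <- length(intersect(head(rankings[[u]], k), relevants[[u]]))
    if (mode == "literal") {
      hits
    } else {
      hits / min(k, length(relevants[[u]]))
    }
  }, numeric(1))
  mean(per_user)
}

#' Accuracy@K curve for k = 1..k_max
#'
#' @inheritParams accuracy_at_k
#' @param k_max Largest cutoff.
#' @return Tibble with columns `k` and `accuracy`.
#' @export
accuracy_curve <- function(rankings, relevants, k_max = 10L,
                           mode = c("normalized", "literal")) {
  mode <- match.arg(mode)
  tibble::tibble(
    k = seq_len(k_max),
    accuracy = vapply(
      seq_len(k_max),
      function(k) suppressWarnings(accuracy_at_k(rankings, relevants, k, mode)),
      numeric(1)
    )
  )
}
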