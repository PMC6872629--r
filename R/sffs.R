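# Internal: validate a two-class label vector, return 0/1 integer codes and
# the level order (first level = code 0).
label_codes <- function(labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2)
    stop("exactly two classes required, got: ", paste(lev, collapse = ", "))
  list(code = as.integer(labels == lev[2]), levels = lev)
}

#' 2-means cluster agreement quality of a feature subset
#'
#' Runs deterministic 2-means on the rows of `X` (farthest-pair
#' initialization: the two rows at maximal Euclidean distance seed the
#' centroids, ties broken by lowest row index; Lloyd iteration to an
#' assignment fixed point, capped at 100 iterations) and returns the
#' fraction of subjects whose cluster matches their label, maximized over
#' the two cluster-to-label pairings. If all rows are identical the quality
#' is the majority-label fraction.
#'
#' @param X numeric matrix, subjects x selected features (at least 1 column).
#' @param labels two-class label vector, both classes present.
#' @return Quality in `[0, 1]`.
#' @export
cluster_quality <- function(X, labels) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("cluster_quality: need at least one feature column")
  lc <- label_codes(labels)
  if (nrow(X) != length(lc$code))
    stop("cluster_quality: one label per row required")
  .cluster_quality_cpp(X, lc$code)
}

#' One SFFS scoring run over a fixed feature ordering
#'
#' Forward pass: starting from an empty subset with reference quality equal
#' to the majority-label fraction, each feature in `ordering` is added (and
#' stays in the subset regardless); its score delta gets +1 if the subset's
#' [cluster_quality()] strictly improved, else -1, and the reference quality
#' is updated. Backward pass: starting from the full subset and its quality,
#' each feature in `ordering` is removed; the removed feature gets +1 if
#' quality dropped without it, -1 otherwise (quality of the empty subset is
#' the majority fraction). Every feature is touched exactly twice, so deltas
#' lie in `{-2, 0, +2}`.
#'
#' @param X a [feature_matrix()] or plain numeric matrix.
#' @param labels two-class labels (ignored if `X` is a [feature_matrix()],
#'   which carries its own).
#' @param ordering permutation of `1:n_features`.
#' @param encode_direction expand direction channels to (sin, cos) pairs for
#'   distance computations (default `TRUE`; only applies to
#'   [feature_matrix()] input).
#' @return Integer vector of per-feature score deltas.
#' @export
sffs_single_run <- function(X, labels = NULL, ordering,
                            encode_direction = TRUE) {
  enc <- .sffs_encode(X, labels, encode_direction)
  p <- length(enc$feat_start)
  if (p < 1) stop("sffs_single_run: empty feature matrix")
  if (!identical(sort(as.integer(ordering)), seq_len(p)))
    stop("sffs_single_run: ordering must be a permutation of all features")
  .sffs_single_run_cpp(enc$X, enc$feat_start, enc$feat_len, enc$code,
                       as.integer(ordering) - 1L)
}

.sffs_encode <- function(X, labels, encode_direction) {
  if (inherits(X, "feature_matrix")) {
    lc <- label_codes(X$labels)
    enc <- encode_features(X, encode_direction)
  } else {
    X <- as.matrix(X)
    lc <- label_codes(labels)
    enc <- list(X = X, feat_start = as.integer(seq_len(ncol(X)) - 1L),
                feat_len = rep(1L, ncol(X)))
  }
  c(enc, list(code = lc$code))
}

#' Accumulated SFFS feature scores over random orderings
#'
#' Sums [sffs_single_run()] deltas over `n_runs` independent uniform random
#' feature orderings drawn from a generator seeded by `seed`. Deterministic
#' for a fixed seed; every feature's aggregate score is bounded by
#' `2 * n_runs` in absolute value.
#'
#' @inheritParams sffs_single_run
#' @param n_runs number of random orderings (default 250).
#' @param seed integer seed for the ordering stream.
#' @return An object of class `feature_scores`: `score` (per-feature
#'   integer), `n_runs`, `ordering_seed`, `descriptors` (when `X` is a
#'   [feature_matrix()]).
#' @export
sffs_score <- function(X, labels = NULL, n_runs = 250, seed = 1,
                       encode_direction = TRUE) {
  if (n_runs < 1) stop("sffs_score: n_runs must be at least 1")
  enc <- .sffs_encode(X, labels, encode_direction)
  p <- length(enc$feat_start)
  if (p < 1) stop("sffs_score: empty feature matrix")
  orderings <- with_seed(seed, {
    vapply(seq_len(n_runs), function(i) sample.int(p) - 1L, integer(p))
  })
  orderings <- matrix(orderings, nrow = p)
  score <- .sffs_runs_cpp(enc$X, enc$feat_start, enc$feat_len, enc$code,
                          orderings)
  structure(list(score = as.integer(score), n_runs = as.integer(n_runs),
                 ordering_seed = as.integer(seed),
                 descriptors = if (inherits(X, "feature_matrix")) X$descriptors),
            class = "feature_scores")
}

#' @export
print.feature_scores <- function(x, ...) {
  cat(sprintf("<feature_scores: %d features over %d runs, top score %d>\n",
              length(x$score), x$n_runs, max(x$score)))
  invisible(x)
}

#' Top-k scoring features
#'
#' Returns the `k` highest-scoring features in descending score order, ties
#' broken by ascending column index.
#'
#' @param scores a `feature_scores` from [sffs_score()].
#' @param k number of features to return (default 5).
#' @return Data frame with `column` (1-based matrix column), `score`, and
#'   the feature descriptors when available.
#' @export
top_k <- function(scores, k = 5) {
  stopifnot(inherits(scores, "feature_scores"))
  p <- length(scores$score)
  if (k > p) stop("top_k: k exceeds the feature count")
  ord <- order(-scores$score, seq_len(p))[seq_len(k)]
  out <- data.frame(column = ord, score = scores$score[ord])
  if (!is.null(scores$descriptors))
    out <- cbind(out, scores$descriptors[ord, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Write SFFS scores as CSV and a top-k list as JSON
#' @param scores a `feature_scores`.
#' @param base output path prefix.
#' @param k how many top features for the JSON summary.
#' @return Invisibly, the CSV path.
#' @export
write_scores <- function(scores, base, k = 5) {
  df <- data.frame(column = seq_along(scores$score), score = scores$score)
  if (!is.null(scores$descriptors)) df <- cbind(df, scores$descriptors)
  write.csv(df, paste0(base, ".csv"), row.names = FALSE)
  jsonlite::write_json(top_k(scores, min(k, length(scores$score))),
                       paste0(base, "_top.json"), dataframe = "rows",
                       digits = NA)
  invisible(paste0(base, ".csv"))
}
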