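#' Train an RBF-kernel SVM on selected features
#'
#' Features are standardized by the training-set mean and standard deviation
#' (sd 0 treated as 1) before fitting; the model carries the standardization
#' for test-time reuse. Default hyperparameters: `C = 1`,
#' `gamma = 1 / (n_features * var(X))` with the overall feature variance
#' computed after standardization (so approximately `1 / n_features`).
#' Decision scores follow the convention positive = second class (the
#' "diseased"/positive level).
#'
#' @param X numeric matrix, training subjects x selected features.
#' @param y two-class label vector; the positive class is `positive` if
#'   given, else the second unique label.
#' @param params list: `cost` (default 1), `gamma` (default NULL = scale
#'   heuristic).
#' @param positive label value scored as positive, or `NULL`.
#' @return An object of class `svm_model`.
#' @export
train_svm <- function(X, y, params = list(), positive = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  lev <- unique(y)
  if (length(lev) != 2) stop("train_svm: training data must contain both classes")
  if (is.null(positive)) positive <- if ("diseased" %in% lev) "diseased" else lev[2]
  if (!positive %in% lev) stop("train_svm: positive label absent from y")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  v <- var(as.vector(Xs))
  gamma <- params$gamma %||% (1 / (ncol(X) * if (v > 0) v else 1))
  fit <- e1071::svm(Xs, factor(y, levels = c(setdiff(lev, positive), positive)),
                    kernel = "radial", cost = params$cost %||% 1,
                    gamma = gamma, scale = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl, positive = positive,
                 gamma = gamma, cost = params$cost %||% 1),
            class = "svm_model")
}

#' Decision scores of an [train_svm()] model
#'
#' @param model an `svm_model`.
#' @param X numeric matrix of subjects x features (training feature order).
#' @return Numeric vector of finite decision scores; positive means the
#'   positive (diseased) class.
#' @export
svm_scores <- function(model, X) {
  stopifnot(inherits(model, "svm_model"))
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  pred <- predict(model$fit, Xs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # e1071 scores positive toward the level named first in the colname
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  s <- as.numeric(dv[, 1])
  if (first != model$positive) s <- -s
  s
}

# Empirical step-ROC of pooled scores: returns the full (fpr, tpr) polyline
# over unique thresholds, starting at (0,0).
.step_roc <- function(scores, is_pos) {
  np <- sum(is_pos); nn <- sum(!is_pos)
  ord <- order(scores, decreasing = TRUE)
  sp <- is_pos[ord]
  sc <- scores[ord]
  tp <- cumsum(sp); fp <- cumsum(!sp)
  keep <- c(diff(sc) != 0, TRUE)  # cut thresholds only between distinct scores
  tpr <- c(0, tp[keep] / max(np, 1))
  fpr <- c(0, fp[keep] / max(nn, 1))
  list(fpr = fpr, tpr = tpr, n_pos = np, n_neg = nn)
}

# TPR of an empirical ROC at each FPR grid value: largest achievable TPR with
# FPR <= f. Returns NA when the round has no positive subjects.
.tpr_at_grid <- function(scores, is_pos, grid) {
  r <- .step_roc(scores, is_pos)
  if (r$n_pos == 0) return(rep(NA_real_, length(grid)))
  vapply(grid, function(f) max(r$tpr[r$fpr <= f + 1e-12]), numeric(1))
}

#' Trapezoidal area under an ROC curve
#'
#' Points are sorted by FPR, `(0, 0)` is prepended and `(1, 1)` appended,
#' and the area is computed by the trapezoid rule. For an empirical
#' step-ROC over pooled scores this equals the Mann-Whitney concordance
#' statistic (ties counted 1/2).
#'
#' @param fpr,tpr numeric vectors in `[0, 1]`.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(fpr, tpr) {
  if (length(fpr) != length(tpr)) stop("auc_trapezoid: length mismatch")
  if (any(fpr < 0 | fpr > 1 | tpr < 0 | tpr > 1, na.rm = TRUE) ||
      any(!is.finite(c(fpr, tpr))))
    stop("auc_trapezoid: values must be finite and within [0, 1]")
  ord <- order(fpr, tpr)
  x <- c(0, fpr[ord], 1); y <- c(0, tpr[ord], 1)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Empirical ROC points of a score vector
#'
#' @param scores numeric decision scores (higher = more positive).
#' @param labels two-class labels.
#' @param positive positive label (default second unique value, or
#'   `"diseased"` when present).
#' @return Data frame of `(fpr, tpr)` step-curve vertices.
#' @export
roc_points <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (is.null(positive)) positive <- if ("diseased" %in% lev) "diseased" else lev[2]
  r <- .step_roc(scores, labels == positive)
  data.frame(fpr = r$fpr, tpr = r$tpr)
}

#' Repeated leave-n-out SVM cross-validation ROC
#'
#' Per round, `n_test` subjects are sampled uniformly without replacement as
#' the test set (splits whose training set is single-class are rejected and
#' redrawn, with the rejection count recorded); an SVM is trained on the
#' rest and the held-out subjects scored. Each round's pooled scores are
#' thresholded to give a TPR value at each of 101 FPR grid points; the mean
#' and variance over rounds are reported per grid point (rounds whose test
#' set contains no positive subject have undefined TPR and are excluded from
#' the per-point averages; their count is recorded). AUC is the trapezoidal
#' area of the mean curve. Deterministic for a fixed seed.
#'
#' @param X numeric matrix, all subjects x selected features.
#' @param y two-class labels.
#' @param n_test held-out subjects per round (default 5), less than the
#'   subject count.
#' @param n_rounds number of random splits (default 1000).
#' @param seed integer seed for the split stream.
#' @param params SVM parameters passed to [train_svm()].
#' @param positive positive class label.
#' @return An object of class `roc_curve`: `fpr_grid`, `mean_tpr`,
#'   `tpr_variance`, `auc`, `n_rounds`, `n_rejected`, `n_no_positive`,
#'   `seed`.
#' @export
leave_n_out_roc <- function(X, y, n_test = 5, n_rounds = 1000, seed = 1,
                            params = list(), positive = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  if (n_test >= n) stop("leave_n_out_roc: n_test must be below the subject count")
  lev <- unique(y)
  if (length(lev) != 2) stop("leave_n_out_roc: both classes required")
  if (is.null(positive)) positive <- if ("diseased" %in% lev) "diseased" else lev[2]
  grid <- seq(0, 1, length.out = 101)
  tpr_rounds <- matrix(NA_real_, n_rounds, length(grid))
  n_rejected <- 0L
  with_seed(seed, {
    for (b in seq_len(n_rounds)) {
      test <- NULL
      for (try in 1:200) {
        cand <- sample.int(n, n_test)
        if (length(unique(y[-cand])) == 2) { test <- cand; break }
        n_rejected <- n_rejected + 1L
      }
      if (is.null(test))
        stop("leave_n_out_roc: could not draw a two-class training split")
      model <- train_svm(X[-test, , drop = FALSE], y[-test], params, positive)
      sc <- svm_scores(model, X[test, , drop = FALSE])
      tpr_rounds[b, ] <- .tpr_at_grid(sc, y[test] == positive, grid)
    }
  })
  .summarize_roc(grid, tpr_rounds, n_rounds, n_rejected, seed)
}

.summarize_roc <- function(grid, tpr_rounds, n_rounds, n_rejected, seed) {
  ok <- !is.na(tpr_rounds[, 1])
  mean_tpr <- colMeans(tpr_rounds[ok, , drop = FALSE])
  tpr_var <- apply(tpr_rounds[ok, , drop = FALSE], 2, var)
  mean_tpr <- cummax(mean_tpr)  # monotone envelope
  structure(list(fpr_grid = grid, mean_tpr = mean_tpr, tpr_variance = tpr_var,
                 auc = auc_trapezoid(grid, mean_tpr),
                 n_rounds = n_rounds, n_rejected = n_rejected,
                 n_no_positive = sum(!ok), seed = seed),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: AUC %.3f over %d rounds (%d no-positive excluded)>\n",
              x$auc, x$n_rounds, x$n_no_positive))
  invisible(x)
}

#' Nested leave-n-out ROC with in-split feature selection
#'
#' Like [leave_n_out_roc()] but the SFFS feature ranking and top-k choice
#' are recomputed inside every training split, so the reported ROC carries
#' no selection bias from the held-out subjects.
#'
#' @param fm a [feature_matrix()] (all candidate features).
#' @param n_test,n_rounds,seed,params as in [leave_n_out_roc()].
#' @param sffs_runs SFFS orderings per split (typically reduced).
#' @param k features selected per split.
#' @param encode_direction see [sffs_score()].
#' @return A `roc_curve`.
#' @export
nested_leave_n_out_roc <- function(fm, n_test = 5, n_rounds = 100, seed = 1,
                                   sffs_runs = 25, k = 5, params = list(),
                                   encode_direction = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$labels
  n <- nrow(fm$values)
  if (n_test >= n) stop("nested_leave_n_out_roc: n_test must be below the subject count")
  positive <- if ("diseased" %in% y) "diseased" else unique(y)[2]
  grid <- seq(0, 1, length.out = 101)
  tpr_rounds <- matrix(NA_real_, n_rounds, length(grid))
  n_rejected <- 0L
  with_seed(seed, {
    for (b in seq_len(n_rounds)) {
      test <- NULL
      for (try in 1:200) {
        cand <- sample.int(n, n_test)
        if (length(unique(y[-cand])) == 2) { test <- cand; break }
        n_rejected <- n_rejected + 1L
      }
      if (is.null(test))
        stop("nested_leave_n_out_roc: could not draw a two-class training split")
      train_fm <- feature_matrix(fm$values[-test, , drop = FALSE],
                                 fm$descriptors, y[-test])
      sel_seed <- sample.int(2^30, 1)
      sc <- sffs_score(train_fm, n_runs = sffs_runs, seed = sel_seed,
                       encode_direction = encode_direction)
      cols <- top_k(sc, min(k, length(sc$score)))$column
      Xsel <- .encode_columns(fm, cols, encode_direction)
      model <- train_svm(Xsel[-test, , drop = FALSE], y[-test], params, positive)
      scores <- svm_scores(model, Xsel[test, , drop = FALSE])
      tpr_rounds[b, ] <- .tpr_at_grid(scores, y[test] == positive, grid)
    }
  })
  .summarize_roc(grid, tpr_rounds, n_rounds, n_rejected, seed)
}

# Extract selected feature columns in SVM-ready (direction-encoded) form.
.encode_columns <- function(fm, cols, encode_direction = TRUE) {
  enc <- encode_features(fm, encode_direction)
  idx <- unlist(lapply(cols, function(j)
    enc$feat_start[j] + seq_len(enc$feat_len[j])))
  enc$X[, idx, drop = FALSE]
}

#' Write an ROC curve as CSV plus a JSON summary
#' @param roc a `roc_curve`.
#' @param base output path prefix.
#' @param extra named list merged into the JSON summary.
#' @return Invisibly, the CSV path.
#' @export
write_roc <- function(roc, base, extra = list()) {
  write.csv(data.frame(fpr = roc$fpr_grid, mean_tpr = roc$mean_tpr,
                       tpr_variance = roc$tpr_variance),
            paste0(base, ".csv"), row.names = FALSE)
  jsonlite::write_json(c(list(auc = roc$auc, n_rounds = roc$n_rounds,
                              n_rejected = roc$n_rejected,
                              n_no_positive = roc$n_no_positive,
                              seed = roc$seed), extra),
                       paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(base, ".csv"))
}
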