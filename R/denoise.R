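#' PCA noise suppression of a cohort feature matrix
#'
#' Columns are mean-centered (no variance scaling) and decomposed by PCA
#' across subjects (observations = subjects, variables = features). The
#' smallest number of leading components whose cumulative explained variance
#' reaches `variance_fraction` is retained, and the data are reconstructed in
#' the original feature space from those components plus the column means.
#' Shape and descriptors are unchanged, so downstream feature selection still
#' operates on per-location features.
#'
#' @param X a [feature_matrix()] with at least 2 subjects.
#' @param variance_fraction target explained-variance fraction in `(0, 1]`
#'   (default 0.95).
#' @return An object of class `pca_result`: `components` (orthonormal
#'   feature-space basis, one column per retained component),
#'   `explained_fraction` (all components, non-increasing), `n_retained`,
#'   `center`, and `reconstructed` (a [feature_matrix()]).
#' @export
pca_denoise <- function(X, variance_fraction = 0.95) {
  stopifnot(inherits(X, "feature_matrix"))
  if (variance_fraction <= 0 || variance_fraction > 1)
    stop("pca_denoise: variance_fraction must be in (0, 1]")
  v <- X$values
  if (nrow(v) < 2) stop("pca_denoise: need at least 2 subjects")
  pc <- prcomp(v, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2                      # n-1 denominator covariance eigenvalues
  total <- sum(ev)
  if (total <= 0) {                    # all columns constant: nothing to do
    frac <- rep(0, length(ev))
    k <- 0L
    recon <- v
  } else {
    frac <- ev / total
    k <- which(cumsum(frac) >= variance_fraction - 1e-12)[1]
    scores <- pc$x[, seq_len(k), drop = FALSE]
    recon <- scores %*% t(pc$rotation[, seq_len(k), drop = FALSE])
    recon <- sweep(recon, 2, pc$center, "+")
  }
  structure(list(components = pc$rotation[, seq_len(max(k, 0)), drop = FALSE],
                 explained_fraction = frac,
                 n_retained = as.integer(k),
                 center = pc$center,
                 reconstructed = feature_matrix(recon, X$descriptors, X$labels)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result: %d component(s) retained (%.1f%% variance)>\n",
              x$n_retained,
              100 * sum(x$explained_fraction[seq_len(x$n_retained)])))
  invisible(x)
}

#' Serialize a PCA result (components, fractions, means) with JSON metadata
#' @param res a `pca_result`.
#' @param base output path prefix.
#' @return Invisibly, the metadata path.
#' @export
write_pca_result <- function(res, base) {
  con <- gzfile(paste0(base, "_components.csv.gz"), "w")
  write.table(res$components, con, sep = ",", row.names = FALSE, col.names = FALSE)
  close(con)
  jsonlite::write_json(list(n_retained = res$n_retained,
                            explained_fraction = res$explained_fraction,
                            center = res$center),
                       paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(base, ".json"))
}
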