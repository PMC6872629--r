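#' 2D affine transform
#'
#' The forward content map `T(x) = L x + t` (about the image center) applied
#' to a query image; applying the transform samples the query at `T^{-1}(y)`
#' so the content moves by `T`.
#'
#' @param linear invertible 2x2 matrix.
#' @param translation length-2 vector, pixels `(row, col)`.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(linear = diag(2), translation = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  if (abs(det(linear)) < 1e-12)
    stop("affine_transform: linear part must be invertible")
  structure(list(linear = linear, translation = as.numeric(translation)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform t=(%.3g, %.3g) L=[%.4g %.4g; %.4g %.4g]>\n",
              x$translation[1], x$translation[2],
              x$linear[1, 1], x$linear[1, 2], x$linear[2, 1], x$linear[2, 2]))
  invisible(x)
}

# Apply an affine content transform to an image matrix by inverse-map
# bilinear sampling about the grid center.
apply_affine <- function(px, transform) {
  n <- dim(px)
  Li <- solve(transform$linear)
  ctr <- (n - 1) / 2
  r <- matrix(rep(seq_len(n[1]) - 1, n[2]), n[1], n[2])
  cc <- matrix(rep(seq_len(n[2]) - 1, each = n[1]), n[1], n[2])
  yr <- r - ctr[1] - transform$translation[1]
  yc <- cc - ctr[2] - transform$translation[2]
  sr <- Li[1, 1] * yr + Li[1, 2] * yc + ctr[1]
  sc <- Li[2, 1] * yr + Li[2, 2] * yc + ctr[2]
  .warp_pull_cpp(px, sr - r, sc - cc)
}

params_to_affine <- function(p) {
  affine_transform(matrix(c(1 + p[1], p[3], p[2], 1 + p[4]), 2, 2), c(p[5], p[6]))
}

#' Affine pre-registration by mean-squared-difference minimization
#'
#' Finds the affine content transform (translation, rotation, scale, shear)
#' of the query that minimizes the mean squared intensity difference to the
#' reference, by multi-resolution gradient-based optimization (BFGS with
#' numerical gradients over the 6 affine parameters). If the query grid
#' differs from the reference grid it is first resampled onto it.
#'
#' @param query,reference [gray_image()]s normalized to `[0, 1]`.
#' @param params list: `levels` (pyramid depth, default 3), `maxit`
#'   (optimizer iterations per level, default 100).
#' @return List with `transform` ([affine_transform()]), `warped`
#'   ([gray_image()]), `mse_before`, `mse_after` (guaranteed
#'   `mse_after <= mse_before`).
#' @export
register_affine <- function(query, reference, params = list()) {
  stopifnot(inherits(query, "gray_image"), inherits(reference, "gray_image"))
  levels <- params$levels %||% 3
  maxit <- params$maxit %||% 100
  q <- query$pixels; r <- reference$pixels
  if (sd(q) == 0 || sd(r) == 0)
    stop("register_affine: zero-variance image, registration ill-posed")
  if (!identical(dim(q), dim(r)))
    q <- .resize_bilinear_cpp(q, nrow(r), ncol(r))
  p <- rep(0, 6)
  for (lev in rev(seq_len(levels))) {
    f <- 2^(lev - 1)
    nr <- max(8L, as.integer(round(nrow(r) / f)))
    nc <- max(8L, as.integer(round(ncol(r) / f)))
    rl <- block_mean_resize(r, nr, nc)
    ql <- block_mean_resize(q, nr, nc)
    sr <- nr / nrow(r)  # pixel scale at this level
    obj <- function(pl) {
      tf <- tryCatch(params_to_affine(pl), error = function(e) NULL)
      if (is.null(tf)) return(1e9)
      mean((apply_affine(ql, tf) - rl)^2)
    }
    # translations live in level pixels: rescale between levels
    pl <- p; pl[5:6] <- p[5:6] * sr
    fit <- optim(pl, obj, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-10))
    p <- fit$par; p[5:6] <- p[5:6] / sr
  }
  mse0 <- mean((q - r)^2)
  tf <- params_to_affine(p)
  warped <- apply_affine(q, tf)
  mse1 <- mean((warped - r)^2)
  if (mse1 > mse0) {  # never worse than no alignment
    tf <- affine_transform()
    warped <- q
    mse1 <- mse0
  }
  list(transform = tf, warped = gray_image(warped, reference$spacing,
                                           query$subject_id),
       mse_before = mse0, mse_after = mse1)
}

#' Demons non-rigid registration
#'
#' Thirion-style additive Demons: at each iteration the per-pixel update is
#' `v = (q(x+u) - r) grad r / (|grad r|^2 + alpha^2 (q(x+u) - r)^2)` (zero
#' where the denominator is below 1e-12), the accumulated field is
#' Gaussian-smoothed after every iteration, and the scheme runs
#' coarse-to-fine over a resolution pyramid. The returned field lives on the
#' reference grid and points into the query (`warp_image(query, field)`
#' approximates the reference). Registration is deterministic and never
#' increases the sum of squared differences; if SSD rises for 10 consecutive
#' iterations the level stops early and the best field seen is kept (flagged
#' in the `diverged` attribute).
#'
#' @param query a [gray_image()] already affine-aligned to the reference.
#' @param reference the reference [gray_image()].
#' @param params list: `iterations_per_level` (default 50), `smoothing_sigma`
#'   (pixels, default 1.5), `levels` (default 3), `alpha` (default 1).
#' @return A [deformation_field()] (convention `"reference-pull"`) with
#'   attributes `ssd_initial`, `ssd_final`, `diverged`.
#' @export
register_demons <- function(query, reference, params = list()) {
  stopifnot(inherits(query, "gray_image"), inherits(reference, "gray_image"))
  iters <- params$iterations_per_level %||% 50
  sigma <- params$smoothing_sigma %||% 1.5
  levels <- params$levels %||% 3
  alpha <- params$alpha %||% 1
  q <- query$pixels; r <- reference$pixels
  if (!all(is.finite(q)) || !all(is.finite(r)))
    stop("register_demons: non-finite intensities")
  if (!identical(dim(q), dim(r)))
    stop("register_demons: query must live on the reference grid")
  ssd0 <- sum((q - r)^2)
  ur <- NULL; uc <- NULL
  diverged <- FALSE
  for (lev in rev(seq_len(levels))) {
    f <- 2^(lev - 1)
    nr <- max(8L, as.integer(round(nrow(r) / f)))
    nc <- max(8L, as.integer(round(ncol(r) / f)))
    rl <- block_mean_resize(r, nr, nc)
    ql <- block_mean_resize(q, nr, nc)
    if (is.null(ur)) {
      ur <- matrix(0, nr, nc); uc <- matrix(0, nr, nc)
    } else {
      rr <- nr / nrow(ur); rc <- nc / ncol(uc)
      ur <- .resize_bilinear_cpp(ur, nr, nc) * rr
      uc <- .resize_bilinear_cpp(uc, nr, nc) * rc
    }
    res <- .demons_level_cpp(ql, rl, ur, uc, as.integer(iters), sigma, alpha)
    ur <- res$ur; uc <- res$uc
    if (isTRUE(res$diverged)) diverged <- TRUE
  }
  warped <- .warp_pull_cpp(q, ur, uc)
  ssd1 <- sum((warped - r)^2)
  if (ssd1 > ssd0) {  # fall back to identity rather than degrade alignment
    ur[] <- 0; uc[] <- 0; ssd1 <- ssd0
  }
  out <- deformation_field(ur, uc, 1, convention = "reference-pull")
  attr(out, "ssd_initial") <- ssd0
  attr(out, "ssd_final") <- ssd1
  attr(out, "diverged") <- diverged
  out
}

#' Warp an image by a deformation field (pull/backward warping)
#'
#' `out(x) = image(x + u(x))` with bilinear interpolation and edge-clamped
#' sampling. The field must be full resolution (`cell_size` 1) on the image
#' grid.
#'
#' @param image a [gray_image()].
#' @param field a [deformation_field()] with the image's grid shape.
#' @return The warped [gray_image()].
#' @export
warp_image <- function(image, field) {
  stopifnot(inherits(image, "gray_image"), inherits(field, "deformation_field"))
  if (!identical(dim(image$pixels), dim(field$u_row)) || field$cell_size != 1)
    stop("warp_image: field grid must match the image grid at cell_size 1")
  gray_image(.warp_pull_cpp(image$pixels, field$u_row, field$u_col),
             image$spacing, image$subject_id)
}

#' Register a subject to the reference (affine then Demons)
#'
#' Convenience wrapper running [register_affine()] followed by
#' [register_demons()] on the affine-aligned query, as the pipeline does.
#'
#' @param query,reference [gray_image()]s.
#' @param affine_params,demons_params parameter lists for the two stages.
#' @return List with `affine` (the [register_affine()] result) and `field`
#'   (the Demons [deformation_field()]).
#' @export
register_subject <- function(query, reference, affine_params = list(),
                             demons_params = list()) {
  aff <- register_affine(query, reference, affine_params)
  field <- register_demons(aff$warped, reference, demons_params)
  list(affine = aff, field = field)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
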