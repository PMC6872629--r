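#' 2D grayscale image container
#'
#' A light wrapper around a numeric matrix of intensities with optional
#' physical pixel spacing and a subject identifier. Pixel coordinates
#' throughout the package are 0-based `(row, col)` with row increasing
#' downward.
#'
#' @param pixels numeric matrix of finite intensities (rows x cols).
#' @param spacing physical size per pixel in mm, length 1 or 2 (row, col).
#' @param subject_id opaque identifier, or `NULL`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, spacing = 1, subject_id = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) == 0L || ncol(pixels) == 0L)
    stop("gray_image: pixel grid must be non-empty")
  if (!all(is.finite(pixels)))
    stop("gray_image: all intensities must be finite")
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  structure(list(pixels = pixels, spacing = as.numeric(spacing),
                 subject_id = subject_id),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, spacing %.3gx%.3g mm%s, range [%.3g, %.3g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              if (is.null(x$subject_id)) "" else paste0(", id=", x$subject_id),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

as_gray_image <- function(x, subject_id = NULL) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x, subject_id = subject_id)
}

#' Dense 2D deformation field
#'
#' Per-grid-point displacement vectors `(u_row, u_col)` in pixels of the
#' original image, defined on a (possibly downsampled) grid. The all-zero
#' field is the identity mapping. The `convention` tag records the direction
#' the field points: `"reference-pull"` fields live on the reference grid and
#' point into a query image (the output of [register_demons()]), while
#' `"generative"` fields warp the reference into a synthetic subject
#' ([make_subject()]).
#'
#' @param u_row,u_col numeric matrices of displacement components (pixels).
#' @param cell_size pixels per grid cell (1 for a full-resolution field).
#' @param convention orientation tag, free-form string.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(u_row, u_col, cell_size = 1,
                              convention = "reference-pull") {
  u_row <- as.matrix(u_row); u_col <- as.matrix(u_col)
  if (!identical(dim(u_row), dim(u_col)))
    stop("deformation_field: component grids must share a shape")
  if (!all(is.finite(u_row)) || !all(is.finite(u_col)))
    stop("deformation_field: all components must be finite")
  if (cell_size <= 0) stop("deformation_field: cell_size must be positive")
  structure(list(u_row = u_row, u_col = u_col,
                 cell_size = as.numeric(cell_size),
                 convention = convention),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  m <- sqrt(x$u_row^2 + x$u_col^2)
  cat(sprintf("<deformation_field %dx%d, cell %.3g px, |u| max %.3g px, %s>\n",
              nrow(x$u_row), ncol(x$u_row), x$cell_size, max(m), x$convention))
  invisible(x)
}

#' @export
dim.deformation_field <- function(x) dim(x$u_row)

zero_field <- function(shape, cell_size = 1, convention = "reference-pull") {
  z <- matrix(0, shape[1], shape[2])
  deformation_field(z, z, cell_size, convention)
}

#' Per-cell displacement magnitude of a deformation field
#' @param field a [deformation_field()].
#' @return Matrix of displacement lengths (pixels).
#' @export
field_magnitude <- function(field) sqrt(field$u_row^2 + field$u_col^2)

#' Compose two deformation fields
#'
#' Returns the field of the composed pull-warp: warping an image by the
#' result equals warping it by `inner` and then warping that by `outer`
#' (up to interpolation). `u(x) = u_outer(x) + u_inner(x + u_outer(x))`,
#' with `u_inner` sampled bilinearly and edge-clamped.
#'
#' @param outer,inner `deformation_field`s on the same full-resolution grid.
#' @return A `deformation_field`.
#' @export
compose_fields <- function(outer, inner) {
  stopifnot(inherits(outer, "deformation_field"), inherits(inner, "deformation_field"))
  if (!identical(dim(outer), dim(inner)))
    stop("compose_fields: grids must match")
  ur <- outer$u_row + .warp_pull_cpp(inner$u_row, outer$u_row, outer$u_col)
  uc <- outer$u_col + .warp_pull_cpp(inner$u_col, outer$u_row, outer$u_col)
  deformation_field(ur, uc, outer$cell_size, outer$convention)
}

#' Numerically invert a deformation field
#'
#' Finds `v` with `x + v(x) + u(x + v(x)) = 0` by fixed-point iteration,
#' i.e. the displacement of the inverse mapping. Used to compare a
#' registration-recovered pull field against a generative ground-truth field,
#' which point in opposite directions.
#'
#' @param field a `deformation_field`.
#' @param n_iter fixed-point iterations (default 30).
#' @return A `deformation_field` of the inverse displacement.
#' @export
invert_field <- function(field, n_iter = 30) {
  stopifnot(inherits(field, "deformation_field"))
  vr <- -field$u_row; vc <- -field$u_col
  for (i in seq_len(n_iter)) {
    vr_new <- -.warp_pull_cpp(field$u_row, vr, vc)
    vc_new <- -.warp_pull_cpp(field$u_col, vr, vc)
    vr <- vr_new; vc <- vc_new
  }
  deformation_field(vr, vc, field$cell_size,
                    convention = paste0("inverse-of-", field$convention))
}

# Gaussian smoothing of a matrix (replicate-padded separable convolution).
smooth_matrix <- function(m, sigma) .gauss_smooth_cpp(as.matrix(m), sigma)

# Area-exact block-mean resize of a matrix to nr2 x nc2 (used by the
# registration pyramid); weights from interval overlaps.
block_mean_resize <- function(m, nr2, nc2) {
  wr <- .overlap_weights(nrow(m), nr2)
  wc <- .overlap_weights(ncol(m), nc2)
  (wr$W %*% m %*% t(wc$W))
}

# Overlap weight matrix mapping a fine axis of length n onto n2 coarse
# intervals of length n/n2; rows normalized to sum 1. Returns the raw cell
# coverage too (for area-weighted statistics).
.overlap_weights <- function(n, n2) {
  cell <- n / n2
  W <- matrix(0, n2, n)
  for (i in seq_len(n2)) {
    lo <- (i - 1) * cell; hi <- i * cell
    j0 <- floor(lo) + 1; j1 <- min(ceiling(hi), n)
    for (j in j0:j1) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[i, j] <- ov
    }
  }
  area <- rowSums(W)
  list(W = W / area, area = area)
}
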