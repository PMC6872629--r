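#' Downsample a deformation field onto a coarser grid
#'
#' Each coarse vector is the area-weighted mean of the fine vectors
#' overlapping its cell (exact block mean for integer cells; box-filter
#' overlap weights for fractional cells such as 3.75). The coarse grid has
#' `ceiling(rows / cell) x ceiling(cols / cell)` cells; displacement values
#' stay in original-image pixels.
#'
#' @param field a [deformation_field()] with `cell_size` 1.
#' @param cell target cell size in pixels, `>= 1` (may be fractional).
#' @return A [deformation_field()] with `cell_size = cell`.
#' @export
downsample_field <- function(field, cell) {
  stopifnot(inherits(field, "deformation_field"))
  if (cell < 1) stop("downsample_field: cell must be >= 1")
  if (cell == 1) return(field)
  n <- dim(field)
  nr2 <- ceiling(n[1] / cell); nc2 <- ceiling(n[2] / cell)
  wr <- .cell_overlap_weights(n[1], cell, nr2)
  wc <- .cell_overlap_weights(n[2], cell, nc2)
  ur <- wr$W %*% field$u_row %*% t(wc$W)
  uc <- wr$W %*% field$u_col %*% t(wc$W)
  deformation_field(ur, uc, cell, field$convention)
}

# Overlap weights for coarse cells [i*cell, (i+1)*cell) over a fine axis of
# length n; the last cell may be partial. Rows normalized to mean weights;
# raw coverage returned for area-weighted statistics.
.cell_overlap_weights <- function(n, cell, n2) {
  W <- matrix(0, n2, n)
  for (i in seq_len(n2)) {
    lo <- (i - 1) * cell; hi <- min(i * cell, n)
    j0 <- floor(lo) + 1; j1 <- min(ceiling(hi), n)
    for (j in j0:j1) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[i, j] <- ov
    }
  }
  area <- rowSums(W)
  list(W = W / area, area = area)
}

# Area (fine-pixel coverage) of every cell of a downsampled grid, row-major.
cell_areas <- function(shape, cell) {
  n2 <- ceiling(shape / cell)
  ar <- .cell_overlap_weights(shape[1], cell, n2[1])$area
  ac <- .cell_overlap_weights(shape[2], cell, n2[2])$area
  as.vector(outer(ar, ac))  # row-varying fastest; only used symmetrically
}

#' Convert a deformation field to polar form
#'
#' Per-cell displacement magnitude `sqrt(u_row^2 + u_col^2)` and direction
#' `atan2(u_row, u_col)` in `(-pi, pi]`; the zero vector maps to `(0, 0)` by
#' convention.
#'
#' @param field a [deformation_field()].
#' @return List of class `polar_field` with `magnitude` and `direction`
#'   matrices and the field's `cell_size`.
#' @export
field_to_polar <- function(field) {
  stopifnot(inherits(field, "deformation_field"))
  mag <- sqrt(field$u_row^2 + field$u_col^2)
  dir <- atan2(field$u_row, field$u_col)
  dir[mag == 0] <- 0
  structure(list(magnitude = mag, direction = dir, cell_size = field$cell_size),
            class = "polar_field")
}

#' Jacobian determinant of a deformation field
#'
#' `det(I + grad u)` per cell, with the displacement gradient computed by
#' central differences (one-sided at borders) at spacing `cell_size`. An
#' identity (zero) field gives 1 everywhere; values below 1 indicate local
#' shrinkage and above 1 local expansion.
#'
#' @param field a [deformation_field()] on a grid of at least 3x3 cells.
#' @return A matrix of determinants (class `jacobian_map`).
#' @export
jacobian_determinant <- function(field) {
  stopifnot(inherits(field, "deformation_field"))
  n <- dim(field)
  if (any(n < 3)) stop("jacobian_determinant: grid must be at least 3x3")
  h <- field$cell_size
  g <- function(m, dir) {
    out <- matrix(0, n[1], n[2])
    if (dir == "row") {
      out[2:(n[1] - 1), ] <- (m[3:n[1], ] - m[1:(n[1] - 2), ]) / (2 * h)
      out[1, ] <- (m[2, ] - m[1, ]) / h
      out[n[1], ] <- (m[n[1], ] - m[n[1] - 1, ]) / h
    } else {
      out[, 2:(n[2] - 1)] <- (m[, 3:n[2]] - m[, 1:(n[2] - 2)]) / (2 * h)
      out[, 1] <- (m[, 2] - m[, 1]) / h
      out[, n[2]] <- (m[, n[2]] - m[, n[2] - 1]) / h
    }
    out
  }
  drr <- g(field$u_row, "row"); drc <- g(field$u_row, "col")
  dcr <- g(field$u_col, "row"); dcc <- g(field$u_col, "col")
  detj <- (1 + drr) * (1 + dcc) - drc * dcr
  structure(detj, class = c("jacobian_map", "matrix"))
}

#' Assemble per-rate cohort feature matrices from deformation fields
#'
#' For each downsampling rate: every subject's field is downsampled, the
#' requested channels are computed, and cells are flattened row-major with
#' channels interleaved per cell (magnitude, direction, jacobian order).
#' Matrices for different rates are kept separate, since each rate is
#' analyzed independently.
#'
#' @param fields list of per-subject full-resolution [deformation_field()]s
#'   on a shared reference grid.
#' @param labels per-subject class labels (two classes).
#' @param rates numeric cell sizes, default `c(3, 3.75, 5)`.
#' @param channels subset of `c("magnitude", "direction", "jacobian")`.
#' @return Named list (one element per rate) of `feature_matrix` objects:
#'   `values` (subjects x features), `descriptors` (data frame with 0-based
#'   `grid_row`, `grid_col`, `channel`, `cell_size`), `labels`.
#' @export
build_feature_matrix <- function(fields, labels,
                                 rates = c(3, 3.75, 5),
                                 channels = c("magnitude", "direction")) {
  channels <- match.arg(channels, c("magnitude", "direction", "jacobian"),
                        several.ok = TRUE)
  if (length(fields) != length(labels))
    stop("build_feature_matrix: one label per field required")
  shp <- dim(fields[[1]])
  for (f in fields)
    if (!identical(dim(f), shp))
      stop("build_feature_matrix: all fields must share the reference grid")
  out <- list()
  for (rate in rates) {
    rows <- lapply(fields, function(f) {
      d <- downsample_field(f, rate)
      chan <- list()
      if (any(c("magnitude", "direction") %in% channels)) {
        p <- field_to_polar(d)
        if ("magnitude" %in% channels) chan$magnitude <- p$magnitude
        if ("direction" %in% channels) chan$direction <- p$direction
      }
      if ("jacobian" %in% channels)
        chan$jacobian <- unclass(jacobian_determinant(d))
      # row-major cells, channels interleaved per cell
      g <- dim(chan[[1]])
      vals <- vapply(chan, function(m) as.vector(t(m)), numeric(prod(g)))
      list(v = as.vector(t(vals)), g = g)
    })
    g <- rows[[1]]$g
    values <- do.call(rbind, lapply(rows, `[[`, "v"))
    ord_chan <- intersect(c("magnitude", "direction", "jacobian"), channels)
    desc <- data.frame(
      grid_row = rep(rep(0:(g[1] - 1), each = g[2] * length(ord_chan))),
      grid_col = rep(rep(0:(g[2] - 1), each = length(ord_chan)), g[1]),
      channel = rep(ord_chan, g[1] * g[2]),
      cell_size = rate,
      stringsAsFactors = FALSE)
    colnames(values) <- sprintf("r%dc%d_%s_s%g", desc$grid_row, desc$grid_col,
                                desc$channel, rate)
    out[[as.character(rate)]] <- feature_matrix(values, desc, labels)
  }
  out
}

#' Feature matrix container
#'
#' @param values subjects x features numeric matrix (finite).
#' @param descriptors data frame with one row per column of `values`:
#'   0-based `grid_row`, `grid_col`, `channel`, `cell_size`.
#' @param labels per-subject class labels.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, descriptors, labels) {
  values <- as.matrix(values)
  if (nrow(descriptors) != ncol(values))
    stop("feature_matrix: one descriptor per column required")
  if (length(labels) != nrow(values))
    stop("feature_matrix: one label per row required")
  if (any(!is.finite(values)))
    stop("feature_matrix: non-finite entries")
  structure(list(values = values, descriptors = descriptors,
                 labels = as.character(labels)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix %d subjects x %d features (cell %s, channels %s)>\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$descriptors$cell_size), collapse = "/"),
              paste(unique(x$descriptors$channel), collapse = "/")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# Expand a feature matrix for Euclidean consumers: each direction column
# becomes the (sin d, cos d) pair so angular distance is continuous at +/-pi.
# The pair is weighted by the cell's cohort-mean displacement magnitude
# (divided by sqrt(2) so the feature's total footprint matches one column):
# the direction of a sub-pixel displacement is numerically meaningless and
# must not out-vote the displacement scale in distance computations, and the
# weighting keeps the two polar channels on commensurate (pixel) scales.
# Label-blind by construction. Falls back to unit weight when no matching
# magnitude channel is present. Returns the expanded matrix plus a CSR map
# feature -> expanded columns.
encode_features <- function(fm, encode_direction = TRUE) {
  p <- ncol(fm$values)
  desc <- fm$descriptors
  circ <- encode_direction & desc$channel == "direction"
  ncols <- ifelse(circ, 2L, 1L)
  start <- cumsum(c(0L, ncols[-p]))
  X <- matrix(0, nrow(fm$values), sum(ncols))
  magcols <- which(desc$channel == "magnitude")
  mag_key <- paste(desc$grid_row[magcols], desc$grid_col[magcols],
                   desc$cell_size[magcols])
  for (j in seq_len(p)) {
    if (circ[j]) {
      m <- magcols[match(paste(desc$grid_row[j], desc$grid_col[j],
                               desc$cell_size[j]), mag_key)]
      w <- if (length(m) == 1 && !is.na(m))
        max(mean(fm$values[, m]), 0) / sqrt(2) else 1 / sqrt(2)
      X[, start[j] + 1] <- w * sin(fm$values[, j])
      X[, start[j] + 2] <- w * cos(fm$values[, j])
    } else X[, start[j] + 1] <- fm$values[, j]
  }
  list(X = X, feat_start = as.integer(start), feat_len = as.integer(ncols))
}

#' Restrict a feature matrix to cells overlapping a tissue mask
#'
#' Drops feature columns whose grid cell has no overlap with the given
#' object mask, so that only tissue-supported deformation features enter
#' selection and classification (deformation values outside the imaged
#' object are regularizer extrapolation, not measurement). Descriptors are
#' preserved for the retained columns.
#'
#' @param fm a [feature_matrix()].
#' @param mask logical matrix on the full-resolution reference grid (`TRUE`
#'   = tissue).
#' @return A [feature_matrix()] with a subset of columns.
#' @export
mask_feature_matrix <- function(fm, mask) {
  stopifnot(inherits(fm, "feature_matrix"))
  keep <- vapply(seq_len(ncol(fm$values)), function(j) {
    s <- fm$descriptors$cell_size[j]
    r0 <- floor(fm$descriptors$grid_row[j] * s) + 1
    r1 <- min(floor((fm$descriptors$grid_row[j] + 1) * s), nrow(mask))
    c0 <- floor(fm$descriptors$grid_col[j] * s) + 1
    c1 <- min(floor((fm$descriptors$grid_col[j] + 1) * s), ncol(mask))
    any(mask[r0:max(r0, r1), c0:max(c0, c1)])
  }, logical(1))
  feature_matrix(fm$values[, keep, drop = FALSE],
                 fm$descriptors[keep, , drop = FALSE], fm$labels)
}

#' Write a feature matrix as CSV plus descriptor JSON
#' @param fm a [feature_matrix()].
#' @param base output path prefix (`<base>.csv`, `<base>_descriptors.json`).
#' @return Invisibly, the CSV path.
#' @export
write_feature_matrix <- function(fm, base) {
  df <- data.frame(label = fm$labels, fm$values, check.names = FALSE)
  write.csv(df, paste0(base, ".csv"), row.names = FALSE)
  jsonlite::write_json(fm$descriptors, paste0(base, "_descriptors.json"),
                       dataframe = "rows", digits = NA)
  invisible(paste0(base, ".csv"))
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param base path prefix used at write time.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(base) {
  df <- read.csv(paste0(base, ".csv"), check.names = FALSE)
  desc <- jsonlite::read_json(paste0(base, "_descriptors.json"),
                              simplifyVector = TRUE)
  feature_matrix(as.matrix(df[, -1, drop = FALSE]), as.data.frame(desc),
                 df$label)
}
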