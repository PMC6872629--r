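#' Map feature descriptors back to reference-image pixel rectangles
#'
#' A descriptor `(row r, col c, cell s)` maps to the half-open 0-based pixel
#' rectangle `[floor(r*s), floor((r+1)*s)) x [floor(c*s), floor((c+1)*s))`,
#' clipped to the image bounds; rectangles of one rate tile the image
#' without overlap. The channel and any score are retained per entry.
#'
#' @param descriptors data frame with 0-based `grid_row`, `grid_col`,
#'   `channel`, `cell_size` (and optionally `score`), as produced by
#'   [top_k()] or [build_feature_matrix()].
#' @param reference_shape `c(rows, cols)` of the reference image.
#' @return An object of class `biomarker_set`: the input descriptors plus
#'   half-open rectangle bounds `row0, row1, col0, col1` (0-based) and
#'   `center_row, center_col` (pixel centers).
#' @export
map_features_to_reference <- function(descriptors, reference_shape) {
  d <- as.data.frame(descriptors)
  need <- c("grid_row", "grid_col", "cell_size")
  if (!all(need %in% names(d)))
    stop("map_features_to_reference: descriptors need ", paste(need, collapse = ", "))
  s <- d$cell_size
  row0 <- floor(d$grid_row * s); row1 <- floor((d$grid_row + 1) * s)
  col0 <- floor(d$grid_col * s); col1 <- floor((d$grid_col + 1) * s)
  if (any(row0 >= reference_shape[1]) || any(col0 >= reference_shape[2]) ||
      any(d$grid_row < 0) || any(d$grid_col < 0))
    stop("map_features_to_reference: descriptor outside the reference grid")
  row1 <- pmin(row1, reference_shape[1])
  col1 <- pmin(col1, reference_shape[2])
  d$row0 <- row0; d$row1 <- row1; d$col0 <- col0; d$col1 <- col1
  d$center_row <- (row0 + row1 - 1) / 2
  d$center_col <- (col0 + col1 - 1) / 2
  structure(d, class = c("biomarker_set", "data.frame"))
}

#' Distance from each biomarker to the nearest known lesion
#'
#' Validation utility for phantom cohorts with planted lesions: for every
#' biomarker rectangle, the Euclidean distance from its pixel center to the
#' nearest lesion center.
#'
#' @param biomarkers a `biomarker_set`.
#' @param lesion_centers non-empty list of 0-based `(row, col)` points.
#' @return Numeric vector, one distance per biomarker entry.
#' @export
localization_error <- function(biomarkers, lesion_centers) {
  if (is.numeric(lesion_centers)) lesion_centers <- list(lesion_centers)
  if (length(lesion_centers) == 0)
    stop("localization_error: lesion list must be non-empty")
  vapply(seq_len(nrow(biomarkers)), function(i) {
    min(vapply(lesion_centers, function(ctr)
      sqrt((biomarkers$center_row[i] - ctr[1])^2 +
           (biomarkers$center_col[i] - ctr[2])^2), numeric(1)))
  }, numeric(1))
}

# Default rate colors: 3 -> red, 3.75 -> green, 5 -> cyan; other rates cycle
# through a fixed palette.
rate_color <- function(cell_size) {
  fixed <- c(`3` = "red", `3.75` = "green", `5` = "cyan")
  key <- as.character(cell_size)
  ifelse(key %in% names(fixed), fixed[key],
         c("magenta", "yellow", "orange")[(seq_along(cell_size) - 1) %% 3 + 1])
}

#' Render biomarker rectangles over the reference image
#'
#' Writes a PNG of the grayscale reference with colored rectangle outlines,
#' one color per downsampling rate (red/green/cyan for cells 3/3.75/5 by
#' default). Pixels outside the outlines are untouched. Deterministic for
#' fixed inputs.
#'
#' @param reference the reference [gray_image()] (intensities in `[0, 1]`).
#' @param sets a `biomarker_set` or list of them (typically one per rate).
#' @param path output PNG path.
#' @param colors optional named vector mapping `cell_size` to color.
#' @return Invisibly, the RGB array written.
#' @export
render_overlay <- function(reference, sets, path, colors = NULL) {
  stopifnot(inherits(reference, "gray_image"))
  if (inherits(sets, "biomarker_set")) sets <- list(sets)
  px <- reference$pixels
  rgb <- array(rep(px, 3), c(nrow(px), ncol(px), 3))
  for (set in sets) {
    if (nrow(set) == 0) next
    for (i in seq_len(nrow(set))) {
      key <- as.character(set$cell_size[i])
      colname <- if (!is.null(colors) && key %in% names(colors)) colors[[key]]
                 else rate_color(set$cell_size[i])
      col3 <- grDevices::col2rgb(colname)[, 1] / 255
      r0 <- set$row0[i] + 1; r1 <- set$row1[i]; c0 <- set$col0[i] + 1; c1 <- set$col1[i]
      for (ch in 1:3) {
        rgb[r0:r1, c(c0, c1), ch] <- col3[ch]
        rgb[c(r0, r1), c0:c1, ch] <- col3[ch]
      }
    }
  }
  png::writePNG(rgb, path)
  invisible(rgb)
}

#' Write a biomarker table as CSV and JSON
#' @param biomarkers a `biomarker_set`.
#' @param base output path prefix.
#' @return Invisibly, the CSV path.
#' @export
write_biomarkers <- function(biomarkers, base) {
  df <- as.data.frame(biomarkers)
  write.csv(df, paste0(base, ".csv"), row.names = FALSE)
  jsonlite::write_json(df, paste0(base, ".json"), dataframe = "rows",
                       digits = NA)
  invisible(paste0(base, ".csv"))
}
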