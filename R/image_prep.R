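#' Load a 2D grayscale image
#'
#' Reads a single-frame image into a [gray_image()]. Supported formats:
#' `"png"` (8/16-bit grayscale; RGB(A) inputs are reduced to luminance),
#' `"tiff"` (8/16-bit), `"dicom"` (single-frame uncompressed explicit-VR
#' little-endian monochrome; `PixelSpacing` is read when present) and
#' `"array"` (a plain CSV matrix of intensities). Intensities are returned as
#' doubles; raster formats arrive pre-scaled to `[0, 1]`.
#'
#' @param path file path.
#' @param format one of `"png"`, `"tiff"`, `"dicom"`, `"array"`; default
#'   guessed from the file extension.
#' @return A [gray_image()] with pixel spacing from DICOM metadata when
#'   available, else 1.
#' @export
load_image <- function(path, format = NULL) {
  if (!file.exists(path)) stop("load_image: file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, png = "png", tif = "tiff", tiff = "tiff",
                     dcm = "dicom", csv = "array",
                     stop("load_image: cannot guess format of ", path))
  }
  format <- match.arg(format, c("png", "tiff", "dicom", "array"))
  id <- tools::file_path_sans_ext(basename(path))
  if (format == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) px <- luminance(px)
    gray_image(px, subject_id = id)
  } else if (format == "tiff") {
    px <- tiff::readTIFF(path)
    if (is.list(px)) stop("load_image: multi-frame TIFF; select one slice: ", path)
    if (length(dim(px)) == 3) px <- luminance(px)
    gray_image(px, subject_id = id)
  } else if (format == "array") {
    px <- as.matrix(read.csv(path, header = FALSE))
    gray_image(unname(px), subject_id = id)
  } else {
    read_dicom_image(path, id)
  }
}

luminance <- function(a) {
  if (dim(a)[3] >= 3) 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  else a[, , 1]
}

# Minimal DICOM reader: explicit-VR little-endian, uncompressed, single-frame
# monochrome. Covers the tags the pipeline needs (Rows, Columns,
# BitsAllocated, PixelRepresentation, PixelSpacing, NumberOfFrames,
# RescaleSlope/Intercept, PixelData); anything fancier is rejected with a
# clear error.
read_dicom_image <- function(path, id = NULL) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  off <- 0L
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") off <- 132L
  u16 <- function(i) as.integer(raw[i + 1]) + 256L * as.integer(raw[i + 2])
  u32 <- function(i) sum(as.double(raw[i + 1:4]) * 256^(0:3))
  pos <- off
  meta <- list(rows = NA, cols = NA, bits = 16L, signed = 0L,
               spacing = c(1, 1), frames = 1L, slope = 1, intercept = 0,
               pixel_data = NULL)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8 <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[pos + 5:6])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); hdr <- 12L
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- u16(pos + 6L); hdr <- 8L
    } else {  # implicit VR fallback
      len <- u32(pos + 4L); hdr <- 8L; vr <- ""
    }
    if (len == 4294967295) stop("read_dicom_image: undefined-length element (compressed or sequence pixel data) unsupported: ", path)
    body <- pos + hdr
    val_raw <- if (len > 0) raw[(body + 1):(body + len)] else raw(0)
    tag <- sprintf("%04x%04x", group, elem)
    if (tag == "00280010") meta$rows <- u16(body)
    else if (tag == "00280011") meta$cols <- u16(body)
    else if (tag == "00280100") meta$bits <- u16(body)
    else if (tag == "00280103") meta$signed <- u16(body)
    else if (tag == "00280008") meta$frames <- as.integer(trimws(rawToChar(val_raw)))
    else if (tag == "00280030") {
      sp <- as.numeric(strsplit(trimws(rawToChar(val_raw)), "\\\\")[[1]])
      if (length(sp) == 2 && all(is.finite(sp))) meta$spacing <- sp
    }
    else if (tag == "00281053") meta$slope <- as.numeric(trimws(rawToChar(val_raw)))
    else if (tag == "00281052") meta$intercept <- as.numeric(trimws(rawToChar(val_raw)))
    else if (tag == "7fe00010") { meta$pixel_data <- val_raw; break }
    pos <- body + len
  }
  if (is.na(meta$rows) || is.na(meta$cols) || is.null(meta$pixel_data))
    stop("read_dicom_image: could not parse image geometry/pixel data: ", path)
  if (!is.na(meta$frames) && meta$frames > 1)
    stop("read_dicom_image: multi-frame DICOM; select a single slice: ", path)
  bytes <- meta$bits / 8
  n <- meta$rows * meta$cols
  if (length(meta$pixel_data) < n * bytes)
    stop("read_dicom_image: truncated pixel data: ", path)
  vals <- readBin(meta$pixel_data, "integer", n = n, size = bytes,
                  signed = (meta$signed == 1L && bytes > 1), endian = "little")
  if (bytes == 1) vals <- as.integer(vals) %% 256L
  else if (meta$signed == 0L) vals <- ifelse(vals < 0, vals + 65536, vals)
  vals <- vals * meta$slope + meta$intercept
  px <- matrix(vals, meta$rows, meta$cols, byrow = TRUE)  # DICOM is row-major
  gray_image(px, spacing = meta$spacing, subject_id = id)
}

#' Crop and intensity-normalize an image
#'
#' Without a `bbox`, auto-crops to the bounding box of the largest connected
#' component above the Otsu threshold, padded by 5 px and clipped to the
#' frame. Intensities are then linearly rescaled so the 1st/99th percentiles
#' (order statistics) map to 0/1, and clipped to `[0, 1]`. A constant image
#' returns all zeros with a warning.
#'
#' @param image a [gray_image()].
#' @param bbox optional 0-based pixel rectangle `c(row0, row1, col0, col1)`
#'   (inclusive) within the image bounds; overrides auto-cropping.
#' @return A cropped, normalized [gray_image()].
#' @export
crop_and_normalize <- function(image, bbox = NULL) {
  stopifnot(inherits(image, "gray_image"))
  px <- image$pixels
  if (diff(range(px)) == 0) {
    warning("crop_and_normalize: constant image; returning all zeros")
    return(gray_image(matrix(0, nrow(px), ncol(px)), image$spacing, image$subject_id))
  }
  if (is.null(bbox)) {
    rng <- range(px)
    thr <- EBImage::otsu(EBImage::Image((px - rng[1]) / diff(rng)), range = c(0, 1))
    lab <- EBImage::bwlabel(EBImage::Image(((px - rng[1]) / diff(rng)) > thr))
    lab <- EBImage::imageData(lab)
    if (max(lab) == 0) {
      bbox <- c(0, nrow(px) - 1, 0, ncol(px) - 1)
    } else {
      biggest <- which.max(tabulate(lab[lab > 0]))
      idx <- which(lab == biggest, arr.ind = TRUE)
      bbox <- c(max(min(idx[, 1]) - 1 - 5, 0), min(max(idx[, 1]) - 1 + 5, nrow(px) - 1),
                max(min(idx[, 2]) - 1 - 5, 0), min(max(idx[, 2]) - 1 + 5, ncol(px) - 1))
    }
  } else {
    if (length(bbox) != 4 || bbox[1] < 0 || bbox[3] < 0 ||
        bbox[2] > nrow(px) - 1 || bbox[4] > ncol(px) - 1 ||
        bbox[1] > bbox[2] || bbox[3] > bbox[4])
      stop("crop_and_normalize: bbox outside image bounds")
  }
  px <- px[(bbox[1] + 1):(bbox[2] + 1), (bbox[3] + 1):(bbox[4] + 1), drop = FALSE]
  q <- quantile(px, c(0.01, 0.99), type = 1, names = FALSE)
  if (q[2] <= q[1]) q <- range(px)
  if (q[2] <= q[1]) {
    warning("crop_and_normalize: constant crop; returning all zeros")
    return(gray_image(matrix(0, nrow(px), ncol(px)), image$spacing, image$subject_id))
  }
  px <- pmin(pmax((px - q[1]) / (q[2] - q[1]), 0), 1)
  gray_image(px, image$spacing, image$subject_id)
}

#' Select the most average-looking reference subject
#'
#' Given a table of per-subject scalar morphometric measurements, each
#' subject is scored by the sum over measurements of its standardized
#' absolute deviation from the cohort mean (`|x - mean| / sd`, with `sd`
#' treated as 1 when zero). The subject with the smallest score is returned;
#' ties break by table row order.
#'
#' @param table data frame with a `subject_id` column plus one or more
#'   numeric measurement columns, no missing values, at least 2 subjects.
#' @return The winning `subject_id` (scalar).
#' @export
select_reference <- function(table) {
  if (!is.data.frame(table) || !"subject_id" %in% names(table))
    stop("select_reference: need a data frame with a subject_id column")
  meas <- table[setdiff(names(table), "subject_id")]
  if (nrow(table) < 2) stop("select_reference: need at least 2 subjects")
  if (ncol(meas) < 1) stop("select_reference: need at least 1 measurement")
  m <- as.matrix(meas)
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("select_reference: measurements must be finite numerics")
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  s[s == 0] <- 1
  score <- rowSums(abs(sweep(sweep(m, 2, mu), 2, s, "/")))
  table$subject_id[which.min(score)]
}

#' Read a cohort manifest CSV (`subject_id, label, path`)
#' @param path manifest path; image paths are resolved relative to it.
#' @return Data frame with absolute `path` column.
#' @export
read_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(man)))
    stop("read_manifest: manifest must have columns ", paste(need, collapse = ", "))
  man$path <- file.path(dirname(path), man$path)
  man
}
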