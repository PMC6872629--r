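#' Specification of a synthetic two-class phantom cohort
#'
#' Defines the study conditions for a simulated deformation-morphometry
#' cohort: a textured reference "head", control subjects obtained from it by
#' a small global affine jitter plus a smooth random deformation plus noise,
#' and diseased subjects that additionally carry localized displacement
#' lesions at known loci. Defaults describe a cohort of 30 subjects (15 per
#' class) of 128 x 128 images with one lesion of peak displacement 3 px and
#' Gaussian radius 8 px.
#'
#' @param image_size pixels per side (square image), at least 32.
#' @param n_control,n_diseased subject counts per class, at least 1 each.
#' @param global_jitter length-2 vector: max rotation (degrees) and max
#'   translation (pixels) of the per-subject global affine jitter.
#' @param smooth_field_amplitude max magnitude (pixels) of the smooth random
#'   deformation shared by both classes.
#' @param smooth_field_scale Gaussian correlation length (pixels) of the
#'   smooth random deformation.
#' @param lesion_centers list of 0-based `(row, col)` pixel coordinates, or a
#'   single `c(row, col)`; `NULL` places one lesion at a default in-object
#'   locus.
#' @param lesion_amplitude peak lesion displacement (pixels, >= 0).
#' @param lesion_radius Gaussian sigma of the lesion bump (pixels, > 0).
#' @param noise_sd additive intensity noise SD (normalized intensity units).
#' @param seed integer master seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 128, n_control = 15, n_diseased = 15,
                         global_jitter = c(3, 3),
                         smooth_field_amplitude = 2, smooth_field_scale = 12,
                         lesion_centers = NULL, lesion_amplitude = 3,
                         lesion_radius = 8, noise_sd = 0.02, seed = 1) {
  if (image_size < 32) stop("phantom_spec: image_size must be at least 32")
  if (n_control < 1 || n_diseased < 1)
    stop("phantom_spec: subject counts must be at least 1")
  if (smooth_field_amplitude < 0 || lesion_amplitude < 0 ||
      lesion_radius <= 0 || noise_sd < 0 || any(global_jitter < 0))
    stop("phantom_spec: amplitudes, radii and noise must be non-negative")
  if (is.null(lesion_centers))
    lesion_centers <- list(round(image_size * c(0.42, 0.58)))
  if (is.numeric(lesion_centers)) lesion_centers <- list(lesion_centers)
  for (ctr in lesion_centers) {
    if (length(ctr) != 2 || any(ctr < 0) || any(ctr > image_size - 1))
      stop("phantom_spec: lesion centers must be 0-based (row, col) inside the image")
  }
  structure(list(image_size = as.integer(image_size),
                 n_control = as.integer(n_control),
                 n_diseased = as.integer(n_diseased),
                 global_jitter = as.numeric(global_jitter),
                 smooth_field_amplitude = smooth_field_amplitude,
                 smooth_field_scale = smooth_field_scale,
                 lesion_centers = lesion_centers,
                 lesion_amplitude = lesion_amplitude,
                 lesion_radius = lesion_radius,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Deterministic per-subject seed stream derived from the master seed.
subject_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(index)) %% 2147483587)
}

# Run expr with a private RNG state seeded by `seed`, restoring the caller's
# RNG afterwards so cohort generation never perturbs the global stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate the textured phantom reference image
#'
#' Builds a deterministic "head" phantom: a large elliptical object on a zero
#' background containing nested elliptical structures, a smooth intensity
#' gradient, and band-limited texture, so that the intensity gradient is
#' non-zero over most of the object and registration is well-posed.
#' Intensities lie in `[0, 1]`; the background is exactly 0.
#'
#' @param spec a [phantom_spec()].
#' @return A [gray_image()] with `subject_id = "reference"`.
#' @export
make_reference <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  with_seed(subject_seed(spec$seed, 0L), {
    r <- matrix(rep(seq_len(n) - 1, n), n, n)        # 0-based row coord
    cc <- matrix(rep(seq_len(n) - 1, each = n), n, n) # 0-based col coord
    ctr <- (n - 1) / 2
    # outer head ellipse
    e1 <- ((r - ctr) / (0.40 * n))^2 + ((cc - ctr) / (0.34 * n))^2
    mask <- e1 <= 1
    img <- matrix(0, n, n)
    # base tissue intensity with a smooth left-right gradient
    img[mask] <- 0.45 + 0.20 * (cc[mask] / n)
    # nested structures: "cranial" ellipse, "ventricle" dark blob, "stem" band
    e2 <- ((r - 0.42 * n) / (0.20 * n))^2 + ((cc - 0.46 * n) / (0.16 * n))^2
    img[e2 <= 1] <- img[e2 <= 1] + 0.25
    e3 <- ((r - 0.40 * n) / (0.07 * n))^2 + ((cc - 0.52 * n) / (0.05 * n))^2
    img[e3 <= 1] <- img[e3 <= 1] - 0.35
    e4 <- ((r - 0.62 * n) / (0.10 * n))^2 + ((cc - 0.62 * n) / (0.22 * n))^2
    img[e4 <= 1] <- img[e4 <= 1] - 0.15
    # band-limited texture everywhere inside the object
    tex <- smooth_matrix(matrix(rnorm(n * n), n, n), 2)
    tex <- tex / max(abs(tex))
    img[mask] <- img[mask] + 0.12 * tex[mask]
    img[mask] <- pmin(pmax(img[mask], 0.08), 1)  # keep object distinct from background
    img[!mask] <- 0
    gray_image(img, subject_id = "reference")
  })
}

# Lesion displacement: Gaussian-windowed displacement bump per lesion center
# with radially symmetric magnitude profile (peak `amplitude` at the center,
# ~0 beyond 3 sigma). The bump direction is fixed per lesion (derived from
# the master seed): the disease displaces the same anatomy in the same
# direction across affected subjects, as a consistent morphological anomaly
# would, so both the magnitude and the direction channel carry a localized
# class signal.
lesion_field <- function(spec, amplitude) {
  n <- spec$image_size
  ur <- matrix(0, n, n); uc <- matrix(0, n, n)
  r <- matrix(rep(seq_len(n) - 1, n), n, n)
  cc <- matrix(rep(seq_len(n) - 1, each = n), n, n)
  for (k in seq_along(spec$lesion_centers)) {
    ctr <- spec$lesion_centers[[k]]
    ang <- with_seed(subject_seed(spec$seed, 100000L + k), runif(1, -pi, pi))
    d2 <- (r - ctr[1])^2 + (cc - ctr[2])^2
    bump <- amplitude * exp(-d2 / (2 * spec$lesion_radius^2))
    ur <- ur + bump * sin(ang)
    uc <- uc + bump * cos(ang)
  }
  deformation_field(ur, uc, 1, convention = "generative")
}

# Smooth stationary random deformation: white-noise vector field convolved
# with a Gaussian of smooth_field_scale, rescaled so max |u| = amplitude.
# Circular (FFT) convolution keeps the field stationary: border-padded
# spatial smoothing would inflate edge variance and hand the normalization
# to a boundary artifact.
smooth_random_field <- function(n, amplitude, scale) {
  if (amplitude <= 0) return(zero_field(c(n, n), convention = "generative"))
  ur <- .circular_gauss(matrix(rnorm(n * n), n, n), scale)
  uc <- .circular_gauss(matrix(rnorm(n * n), n, n), scale)
  mx <- max(sqrt(ur^2 + uc^2))
  if (mx > 0) { ur <- ur * amplitude / mx; uc <- uc * amplitude / mx }
  deformation_field(ur, uc, 1, convention = "generative")
}

# Circular 2D Gaussian convolution via FFT (unit-sum kernel, wrap-around).
.circular_gauss <- function(m, sigma) {
  n <- dim(m)
  g1 <- function(len) {
    x <- c(0:(len %/% 2), -((len - len %/% 2 - 1):1))
    k <- exp(-0.5 * (x / sigma)^2)
    k / sum(k)
  }
  K <- outer(g1(n[1]), g1(n[2]))
  Re(stats::fft(stats::fft(m) * stats::fft(K), inverse = TRUE)) / prod(n)
}

# Global affine jitter as a displacement field: rotation about the image
# center plus translation, both uniform within the configured bounds.
affine_jitter_field <- function(n, rot_deg, trans_px) {
  th <- if (rot_deg > 0) runif(1, -rot_deg, rot_deg) * pi / 180 else 0
  tr <- if (trans_px > 0) runif(2, -trans_px, trans_px) else c(0, 0)
  r <- matrix(rep(seq_len(n) - 1, n), n, n)
  cc <- matrix(rep(seq_len(n) - 1, each = n), n, n)
  ctr <- (n - 1) / 2
  dr <- r - ctr; dc <- cc - ctr
  ur <- (cos(th) * dr - sin(th) * dc) + ctr + tr[1] - r
  uc <- (sin(th) * dr + cos(th) * dc) + ctr + tr[2] - cc
  deformation_field(ur, uc, 1, convention = "generative")
}

#' Generate one phantom subject
#'
#' The subject image is the reference pull-warped by the composition
#' (global affine jitter then smooth random field then, for diseased
#' subjects, the lesion field) with additive Gaussian intensity noise. The
#' returned field is the exact composed generative ground truth on the
#' reference grid: warping the reference by it reproduces the noise-free
#' subject image. Diseased subjects receive a per-subject lesion amplitude
#' jittered uniformly within +/-10% of `spec$lesion_amplitude`.
#'
#' @param reference the cohort reference [gray_image()].
#' @param label `"control"` or `"diseased"`.
#' @param spec a [phantom_spec()].
#' @param seed integer seed for this subject's private random stream.
#' @return A list with elements `image` ([gray_image()]) and `field`
#'   (generative [deformation_field()]).
#' @export
make_subject <- function(reference, label, spec, seed) {
  stopifnot(inherits(reference, "gray_image"), inherits(spec, "phantom_spec"))
  label <- match.arg(label, c("control", "diseased"))
  n <- spec$image_size
  with_seed(seed, {
    u <- affine_jitter_field(n, spec$global_jitter[1], spec$global_jitter[2])
    u <- compose_fields(u, smooth_random_field(n, spec$smooth_field_amplitude,
                                               spec$smooth_field_scale))
    if (label == "diseased" && spec$lesion_amplitude > 0) {
      amp <- spec$lesion_amplitude * runif(1, 0.9, 1.1)
      u <- compose_fields(u, lesion_field(spec, amp))
    }
    img <- .warp_pull_cpp(reference$pixels, u$u_row, u$u_col)
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(n * n, sd = spec$noise_sd), n, n)
    img <- pmin(pmax(img, 0), 1)
    list(image = gray_image(img), field = u)
  })
}

#' Generate a full phantom cohort
#'
#' Produces `n_control + n_diseased` subjects with per-subject seeds derived
#' deterministically from `spec$seed`, plus the shared reference image. The
#' whole cohort is bit-identical across calls with the same spec.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_cohort`: list with `reference`,
#'   `subjects` (each `image`, `label`, `field`, `subject_id`, `seed`) and
#'   `lesion_centers`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  reference <- make_reference(spec)
  labels <- c(rep("control", spec$n_control), rep("diseased", spec$n_diseased))
  subjects <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sd_i <- subject_seed(spec$seed, i)
    s <- make_subject(reference, labels[i], spec, sd_i)
    s$image$subject_id <- sprintf("S%03d", i)
    subjects[[i]] <- list(image = s$image, label = labels[i], field = s$field,
                          subject_id = s$image$subject_id, seed = sd_i)
  }
  structure(list(reference = reference, subjects = subjects,
                 lesion_centers = spec$lesion_centers, spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  labs <- vapply(x$subjects, `[[`, "", "label")
  cat(sprintf("<phantom_cohort: %d control + %d diseased, %dx%d px>\n",
              sum(labs == "control"), sum(labs == "diseased"),
              nrow(x$reference$pixels), ncol(x$reference$pixels)))
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' Writes each subject image as a lossless 16-bit TIFF (or 8-bit PNG), the
#' reference image, a manifest CSV (`subject_id, label, seed, path`) and the
#' generative ground-truth fields as gzip-compressed CSV pairs with a JSON
#' sidecar recording grid shape, cell size and orientation convention.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if missing).
#' @param format `"tiff"` (16-bit, default) or `"png"` (8-bit).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "fields"), showWarnings = FALSE)
  ext <- if (format == "tiff") ".tif" else ".png"
  write_img <- function(img, path) {
    if (format == "tiff") tiff::writeTIFF(img, path, bits.per.sample = 16L,
                                          compression = "LZW")
    else png::writePNG(img, path)
  }
  write_img(cohort$reference$pixels, file.path(dir, paste0("reference", ext)))
  rows <- lapply(cohort$subjects, function(s) {
    p <- file.path(dir, paste0(s$subject_id, ext))
    write_img(s$image$pixels, p)
    fbase <- file.path(dir, "fields", s$subject_id)
    write_field(s$field, fbase)
    data.frame(subject_id = s$subject_id, label = s$label, seed = s$seed,
               path = paste0(s$subject_id, ext), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Serialize a deformation field
#'
#' Writes `<base>_row.csv.gz` / `<base>_col.csv.gz` (plain CSV matrices,
#' gzip-compressed) and `<base>.json` with grid shape, cell size and the
#' orientation convention tag.
#'
#' @param field a `deformation_field`.
#' @param base output path prefix.
#' @return Invisibly, the sidecar path.
#' @export
write_field <- function(field, base) {
  for (comp in c("row", "col")) {
    con <- gzfile(paste0(base, "_", comp, ".csv.gz"), "w")
    write.table(field[[paste0("u_", comp)]], con, sep = ",",
                row.names = FALSE, col.names = FALSE)
    close(con)
  }
  sidecar <- paste0(base, ".json")
  jsonlite::write_json(list(grid_shape = dim(field$u_row),
                            cell_size = field$cell_size,
                            convention = field$convention),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a deformation field written by [write_field()]
#' @param base path prefix used at write time.
#' @return A `deformation_field`.
#' @export
read_field <- function(base) {
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  rd <- function(comp)
    as.matrix(read.csv(gzfile(paste0(base, "_", comp, ".csv.gz")), header = FALSE))
  ur <- unname(rd("row")); uc <- unname(rd("col"))
  deformation_field(ur, uc, meta$cell_size, meta$convention)
}
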