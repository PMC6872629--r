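#' Validate an experiment configuration
#'
#' Accepts a YAML/JSON file path or a plain list, fills defaults (rates
#' `c(3, 3.75, 5)`, channels magnitude + direction, PCA fraction 0.95, 250
#' SFFS runs, top 5 features, leave-5-out with 1000 rounds, pooled selection) and
#' reports every invalid field together. A master `seed` is required; every
#' stage seed is derived from it.
#'
#' @param config path to a YAML/JSON config, or a named list.
#' @return A validated config list of class `experiment_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("validate_config: config must be a list or file path")
  defaults <- list(rates = c(3, 3.75, 5),
                   channels = c("magnitude", "direction"),
                   pca_fraction = 0.95,
                   sffs_runs = 250,
                   top_k = 5,
                   n_test = 5,
                   n_rounds = 1000,
                   mode = "pooled",
                   encode_direction = TRUE,
                   mask_background = TRUE,
                   nested_sffs_runs = 25,
                   svm = list(cost = 1),
                   registration = list(),
                   outdir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  errs <- character(0)
  if (is.null(config$seed)) errs <- c(errs, "missing required field: seed")
  if (any(config$rates <= 0)) errs <- c(errs, "rates must be positive")
  if (config$pca_fraction <= 0 || config$pca_fraction > 1)
    errs <- c(errs, "pca_fraction must be in (0, 1]")
  if (config$top_k < 1) errs <- c(errs, "top_k must be at least 1")
  if (config$sffs_runs < 1) errs <- c(errs, "sffs_runs must be at least 1")
  if (config$n_test < 1) errs <- c(errs, "n_test must be at least 1")
  if (config$n_rounds < 1) errs <- c(errs, "n_rounds must be at least 1")
  if (!config$mode %in% c("pooled", "nested"))
    errs <- c(errs, "mode must be 'pooled' or 'nested'")
  bad_chan <- setdiff(config$channels, c("magnitude", "direction", "jacobian"))
  if (length(bad_chan))
    errs <- c(errs, paste("unknown channels:", paste(bad_chan, collapse = ", ")))
  if (is.null(config$phantom) && is.null(config$manifest))
    errs <- c(errs, "either a phantom spec or an input manifest is required")
  if (length(errs))
    stop("validate_config: ", paste(errs, collapse = "; "))
  if (!is.null(config$phantom) && !inherits(config$phantom, "phantom_spec"))
    config$phantom <- do.call(phantom_spec,
                              c(config$phantom[setdiff(names(config$phantom), "seed")],
                                list(seed = config$phantom$seed %||% config$seed)))
  structure(config, class = c("experiment_config", "list"))
}

# Stage seeds derived deterministically from the master seed.
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 2654435 + sum(utf8ToInt(stage)) * 97) %% 2147483587)
}

#' Run the full biomarker-discovery experiment
#'
#' Executes the pipeline: cohort input (phantom generation or manifest
#' loading + preprocessing), affine + Demons registration of every subject
#' to the reference, per-rate feature extraction, PCA denoising, SFFS
#' scoring with top-k selection, SVM leave-n-out ROC, and biomarker mapping.
#' Two evaluation modes: `"pooled"` selects features once on all subjects and
#' then cross-validates the classifier on them (the reference protocol,
#' optimistic on null data); `"nested"` re-runs feature selection inside
#' every training split (leakage-free). If `config$outdir` is set, all
#' artifacts (manifest, fields, feature/score/ROC CSVs, overlay PNGs,
#' provenance JSON) are written there.
#'
#' @param config an `experiment_config` (or list/path accepted by
#'   [validate_config()]).
#' @return An `experiment_report`: per-rate `scores`, `top`, `roc`,
#'   `biomarkers`, plus `reference`, `labels`, `provenance`.
#' @export
run_experiment <- function(config) {
  config <- validate_config(config)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, t) {
    timings[[stage]] <<- as.numeric(Sys.time() - t, units = "secs")
    Sys.time()
  }

  # --- cohort input ----------------------------------------------------------
  t <- Sys.time()
  if (!is.null(config$phantom)) {
    cohort <- generate_cohort(config$phantom)
    reference <- cohort$reference
    images <- lapply(cohort$subjects, `[[`, "image")
    labels <- vapply(cohort$subjects, `[[`, "", "label")
    lesion_centers <- if (config$phantom$lesion_amplitude > 0)
      cohort$lesion_centers else list()
  } else {
    man <- read_manifest(config$manifest)
    images <- lapply(seq_len(nrow(man)), function(i) {
      img <- load_image(man$path[i])
      img$subject_id <- man$subject_id[i]
      crop_and_normalize(img)
    })
    labels <- man$label
    ref_id <- if (!is.null(config$reference_id)) config$reference_id
      else if (!is.null(config$morphometrics))
        select_reference(read.csv(config$morphometrics, stringsAsFactors = FALSE))
      else stop("run_experiment: manifest input needs reference_id or morphometrics")
    ref_idx <- match(ref_id, man$subject_id)
    if (is.na(ref_idx)) stop("run_experiment: reference subject not in manifest: ", ref_id)
    reference <- images[[ref_idx]]
    # resample everyone onto the reference grid for registration
    images <- lapply(images, function(im) {
      if (identical(dim(im$pixels), dim(reference$pixels))) im
      else gray_image(.resize_bilinear_cpp(im$pixels, nrow(reference$pixels),
                                           ncol(reference$pixels)),
                      reference$spacing, im$subject_id)
    })
    lesion_centers <- list()
  }
  if (length(unique(labels)) != 2)
    stop("run_experiment: cohort must contain exactly two classes")
  t <- tick("input", t)

  # --- registration ----------------------------------------------------------
  fields <- lapply(images, function(img) {
    reg <- register_subject(img, reference,
                            affine_params = config$registration,
                            demons_params = config$registration)
    reg$field
  })
  t <- tick("registration", t)

  # --- per-rate features -> PCA -> SFFS -> ROC -> biomarkers -----------------
  feats <- build_feature_matrix(fields, labels, rates = config$rates,
                                channels = config$channels)
  t <- tick("features", t)
  rates_out <- list()
  for (rate in names(feats)) {
    fm <- feats[[rate]]
    if (isTRUE(config$mask_background))
      fm <- mask_feature_matrix(fm, reference$pixels > 0)
    fm <- pca_denoise(fm, config$pca_fraction)$reconstructed
    sc <- sffs_score(fm, n_runs = config$sffs_runs,
                     seed = stage_seed(config$seed, paste0("sffs", rate)),
                     encode_direction = config$encode_direction)
    top <- top_k(sc, min(config$top_k, length(sc$score)))
    if (config$mode == "pooled") {
      Xsel <- .encode_columns(fm, top$column, config$encode_direction)
      roc <- leave_n_out_roc(Xsel, fm$labels, n_test = config$n_test,
                             n_rounds = config$n_rounds,
                             seed = stage_seed(config$seed, paste0("cv", rate)),
                             params = config$svm)
    } else {
      roc <- nested_leave_n_out_roc(fm, n_test = config$n_test,
                                    n_rounds = config$n_rounds,
                                    seed = stage_seed(config$seed, paste0("cv", rate)),
                                    sffs_runs = config$nested_sffs_runs,
                                    k = config$top_k, params = config$svm,
                                    encode_direction = config$encode_direction)
    }
    bm <- map_features_to_reference(top[, c("grid_row", "grid_col", "channel",
                                            "cell_size", "score")],
                                    dim(reference$pixels))
    loc <- if (length(lesion_centers)) localization_error(bm, lesion_centers)
           else NULL
    rates_out[[rate]] <- list(features = fm, scores = sc, top = top, roc = roc,
                              biomarkers = bm, localization = loc)
  }
  t <- tick("analysis", t)

  report <- structure(list(rates = rates_out, reference = reference,
                           labels = labels, lesion_centers = lesion_centers,
                           config = config,
                           provenance = list(
                             mode = config$mode, seed = config$seed,
                             timings = timings,
                             total_secs = as.numeric(Sys.time() - t0, units = "secs"))),
                      class = "experiment_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report: %s mode, %d subjects>\n",
              x$provenance$mode, length(x$labels)))
  for (rate in names(x$rates)) {
    r <- x$rates[[rate]]
    cat(sprintf("  rate %-5s AUC %.3f top-5 scores [%s]%s\n", rate, r$roc$auc,
                paste(r$top$score, collapse = ", "),
                if (!is.null(r$localization))
                  sprintf(" localization (px): %s",
                          paste(sprintf('%.1f', r$localization), collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' Write all experiment artifacts to a directory
#'
#' @param report an `experiment_report`.
#' @param outdir output directory (created if missing).
#' @return Invisibly, `outdir`.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(mode = report$provenance$mode,
                  seed = report$provenance$seed,
                  n_subjects = length(report$labels),
                  timings = report$provenance$timings,
                  rates = list())
  all_bm <- list()
  for (rate in names(report$rates)) {
    r <- report$rates[[rate]]
    tag <- gsub("\\.", "_", paste0("rate", rate))
    write_feature_matrix(r$features, file.path(outdir, paste0("features_", tag)))
    write_scores(r$scores, file.path(outdir, paste0("scores_", tag)),
                 k = nrow(r$top))
    write_roc(r$roc, file.path(outdir, paste0("roc_", tag)),
              extra = list(rate = as.numeric(rate)))
    write_biomarkers(r$biomarkers, file.path(outdir, paste0("biomarkers_", tag)))
    all_bm[[rate]] <- r$biomarkers
    summary$rates[[rate]] <- list(auc = r$roc$auc, top_scores = r$top$score,
                                  localization = r$localization)
  }
  render_overlay(report$reference, all_bm, file.path(outdir, "overlay.png"))
  png::writePNG(report$reference$pixels, file.path(outdir, "reference.png"))
  jsonlite::write_json(summary, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
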