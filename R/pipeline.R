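# End-to-end orchestration: slide -> tiles -> per-feature confidences ->
# continuous scores -> discrete scores -> report table.
#
# Classifier backends are pluggable per feature: a trained `nash_cnn`, or
# a mock classifier that emits confidences straight from a synthetic
# slide's known label map. The mock separates orchestration correctness
# from model quality and makes pipeline runs exactly reproducible.

#' Mock classifier backed by a known tile label map
#'
#' Emits per-tile confidence vectors from the ground-truth labels of a
#' synthetic slide instead of looking at pixels: one-hot vectors when
#' `noise_concentration` is infinite (default), Dirichlet-perturbed ones
#' otherwise.
#'
#' @param labels Matrix of tile labels as produced by [generate_wsi()].
#' @param feature A [feature_spec()] or feature name.
#' @param noise_concentration Dirichlet concentration (`Inf` = one-hot).
#' @param seed Integer seed used when noise is enabled.
#' @return A `mock_classifier`.
#' @export
mock_classifier <- function(labels, feature, noise_concentration = Inf,
                            seed = 1L) {
  spec <- if (inherits(feature, "feature_spec")) feature else feature_spec(feature)
  if (!is.matrix(labels)) labels <- matrix(labels, nrow = 1)
  structure(list(labels = labels, feature = spec,
                 noise_concentration = noise_concentration, seed = seed),
            class = "mock_classifier")
}

# Confidences for the tiles of a grid, from either backend.
classify_tiles <- function(classifier, image, grid) {
  scale <- attr(grid, "scale")
  if (inherits(classifier, "mock_classifier")) {
    spec <- classifier$feature
    C <- spec$n_classes
    idx <- vapply(seq_len(nrow(grid)), function(i) {
      resolve_class(spec, classifier$labels[grid$row[i] + 1L,
                                            grid$col[i] + 1L])
    }, 0L)
    if (is.infinite(classifier$noise_concentration)) {
      q <- matrix(0, nrow(grid), C)
      q[cbind(seq_len(nrow(grid)), idx + 1L)] <- 1
    } else {
      q <- local_seed(classifier$seed,
                      rdirichlet_rows(idx, C, classifier$noise_concentration))
    }
    colnames(q) <- class_labels(spec)
    return(q)
  }
  tiles <- lapply(seq_len(nrow(grid)), function(i) {
    extract_tile(image, grid[i, ], scale)
  })
  predict(classifier, tiles)
}

#' Run the full scoring pipeline
#'
#' For each slide and requested feature: tile the slide at the feature's
#' scale (low for fibrosis, high otherwise), obtain per-tile confidences,
#' filter ignore-dominated tiles, renormalize, aggregate to the
#' continuous score x, and (when thresholds are given) map x to the
#' discrete pathologist-like score. Slides where every tile is
#' ignore-dominated are reported with `NA` scores and the run continues.
#'
#' @param config A list (or YAML path, see details) with elements:
#'   `slides` — list of `list(id, image)` (RGB array or path);
#'   `features` — feature names to score;
#'   `classifiers` — named list (by feature) of `nash_cnn` /
#'   [mock_classifier()] objects or checkpoint paths;
#'   `thresholds` — optional named list of [threshold_set()] objects,
#'   cut vectors, or JSON paths;
#'   `min_retained` — low-retention warning threshold (default 10);
#'   `out_dir` — optional output directory for `report.csv` and
#'   `manifest.json`; `seed` — recorded in the manifest.
#' @return Data frame: one row per (slide, feature) with `sample_id`,
#'   `feature`, `x`, `discrete`, `n_tiles`, `n_retained`,
#'   `low_retention`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(is.list(config$slides), length(config$features) >= 1)
  min_ret <- config$min_retained %||% 10L
  rows <- list()
  for (slide in config$slides) {
    image <- slide$image
    if (is.character(image)) image <- read_slide(image)
    for (feat in config$features) {
      classifier <- config$classifiers[[feat]]
      if (is.null(classifier)) {
        stop(sprintf("no classifier for feature '%s'", feat), call. = FALSE)
      }
      if (is.character(classifier)) classifier <- load_checkpoint(classifier)
      spec <- feature_spec(feat)
      d <- dim(image)
      grid <- grid_tiles(d[2], d[1], spec$scale, slide_id = slide$id)
      q <- classify_tiles(classifier, image, grid)
      res <- tryCatch(
        aggregate_liver(q, sample_id = slide$id, feature = feat,
                        min_retained = min_ret),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("slide %s / %s: %s", slide$id, feat,
                        conditionMessage(res)), call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = slide$id, feature = feat, x = NA_real_,
          discrete = NA_integer_, n_tiles = nrow(q), n_retained = 0L,
          low_retention = TRUE, stringsAsFactors = FALSE)
        next
      }
      thr <- config$thresholds[[feat]]
      if (is.character(thr)) thr <- read_thresholds_json(thr)
      discrete <- if (is.null(thr)) NA_integer_ else map_score(res$x, thr)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = slide$id, feature = feat, x = res$x,
        discrete = discrete, n_tiles = res$n_tiles_total,
        n_retained = res$n_tiles_retained,
        low_retention = res$low_retention, stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(config$out_dir, "report.csv"),
                     row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("nashscoreR")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed %||% NA,
      features = config$features,
      n_slides = length(config$slides))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  report
}

#' Read a pipeline configuration from YAML
#'
#' YAML fields mirror [run_pipeline()]'s config list; `classifiers` and
#' `thresholds` map feature names to checkpoint / JSON paths, and slides
#' are given as `id:`/`path:` pairs.
#'
#' @param path YAML file path.
#' @return A config list ready for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$slides <- lapply(y$slides, function(s) list(id = s$id, image = s$path))
  y$features <- as.character(y$features)
  y
}
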