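#' Histological feature specifications
#'
#' The four Kleiner-score features are scored from tile classifiers with
#' feature-specific class taxonomies. Every taxonomy carries a trailing
#' "ignore" class for non-tissue/artifact tiles, so the softmax output
#' length is the number of real classes plus one:
#' ballooning 3, inflammation 4, steatosis 5, fibrosis 6.
#'
#' Fibrosis is scored on low-magnification tiles (897 px source squares
#' downscaled 1:3 to 299 px, 1.32 um/px) because bridging and cirrhotic
#' structures need the larger field of view; the other three features use
#' high-magnification tiles (299 px at 0.44 um/px, no downscaling).
#'
#' @param feature One of `"ballooning"`, `"inflammation"`, `"steatosis"`,
#'   `"fibrosis"`.
#' @return A `feature_spec` list with fields `feature`, `classes` (ordered
#'   integer labels of the non-ignore classes), `n_classes` (count including
#'   ignore), `ignore_index` (0-based index of the ignore class, always the
#'   last), `scale` (`"high"` or `"low"`), `tile_px`, `source_px`,
#'   `downscale`, `um_per_px`.
#' @examples
#' fs <- feature_spec("fibrosis")
#' fs$n_classes     # 6
#' fs$scale         # "low"
#' @export
feature_spec <- function(feature = c("ballooning", "inflammation",
                                     "steatosis", "fibrosis")) {
  feature <- match.arg(feature)
  classes <- switch(feature,
    ballooning   = 0:1,
    inflammation = 0:2,
    steatosis    = 0:3,
    fibrosis     = 0:4
  )
  scale <- if (feature == "fibrosis") "low" else "high"
  structure(list(
    feature      = feature,
    classes      = classes,
    n_classes    = length(classes) + 1L,
    ignore_index = length(classes),
    has_ignore   = TRUE,
    scale        = scale,
    tile_px      = 299L,
    source_px    = if (scale == "low") 897L else 299L,
    downscale    = if (scale == "low") 3L else 1L,
    um_per_px    = if (scale == "low") 1.32 else 0.44
  ), class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> %s: classes {%s} + ignore, %s scale (%g um/px)\n",
              x$feature, paste(x$classes, collapse = ","), x$scale,
              x$um_per_px))
  invisible(x)
}

#' Names of the four scored features
#' @return Character vector in canonical order.
#' @export
feature_names <- function() {
  c("ballooning", "inflammation", "steatosis", "fibrosis")
}

#' Class labels including the ignore class
#'
#' @param spec A [feature_spec()].
#' @return Character vector: the integer labels followed by `"ignore"`.
#' @export
class_labels <- function(spec) {
  c(as.character(spec$classes), "ignore")
}

# Resolve a class label (integer or "ignore") to a 0-based class index.
resolve_class <- function(spec, true_class) {
  if (identical(true_class, "ignore")) return(spec$ignore_index)
  cl <- suppressWarnings(as.integer(true_class))
  if (is.na(cl) || !(cl %in% spec$classes)) {
    stop(sprintf("invalid class '%s' for feature '%s'", true_class,
                 spec$feature), call. = FALSE)
  }
  cl
}
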