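# Classical-CV pre-labeling of steatosis tiles: detect bright, round
# vacuoles, sum their area fraction and assign the tile class by the same
# half-open intervals used for the macroscopic steatosis sub-score.

#' Steatosis area fraction and tile class by classical computer vision
#'
#' Segments bright regions (Otsu threshold on luminance unless an explicit
#' `brightness_threshold` is given), keeps connected components whose
#' roundness \eqn{4\pi A / P^2} and pixel area fall inside the configured
#' ranges, sums the retained area, and assigns the class by the half-open
#' intervals 0: <5%, 1: >=5% and <33%, 2: >=33% and <66%, 3: >=66%.
#'
#' @param tile 299 x 299 x 3 RGB array in \[0, 1\].
#' @param brightness_threshold Luminance threshold in \[0, 1\]; `NULL`
#'   (default) uses Otsu's method.
#' @param roundness_range Numeric length-2; components kept if roundness
#'   falls inside (default `c(0.5, 1.5)` — discretised perimeters can push
#'   the isoperimetric quotient slightly above 1).
#' @param size_range Component area range in px^2 (default 30–3000).
#' @return List: `area_fraction` in \[0, 1\] and `class` in 0–3.
#' @examples
#' dark <- array(0.1, dim = c(299, 299, 3))
#' steatosis_area_label(dark)$class  # 0
#' @export
steatosis_area_label <- function(tile, brightness_threshold = NULL,
                                 roundness_range = c(0.5, 1.5),
                                 size_range = c(30, 3000)) {
  d <- dim(tile)
  stopifnot(length(d) == 3L, d[3] >= 3L)
  lum <- 0.299 * tile[, , 1] + 0.587 * tile[, , 2] + 0.114 * tile[, , 3]
  thr <- brightness_threshold %||% tryCatch(
    EBImage::otsu(EBImage::Image(t(lum)), range = c(0, 1)),
    error = function(e) 0.8)
  bw <- lum > thr
  frac <- 0
  if (any(bw)) {
    lab <- EBImage::bwlabel(EBImage::Image(t(bw) * 1))
    sh <- EBImage::computeFeatures.shape(lab)
    if (!is.null(sh) && nrow(sh) > 0) {
      area <- sh[, "s.area"]
      per <- pmax(sh[, "s.perimeter"], 1)
      roundness <- 4 * pi * area / per^2
      keep <- area >= size_range[1] & area <= size_range[2] &
        roundness >= roundness_range[1] & roundness <= roundness_range[2]
      frac <- sum(area[keep]) / (d[1] * d[2])
    }
  }
  list(area_fraction = frac, class = steatosis_class_from_fraction(frac))
}

#' Steatosis tile class from a vacuole area fraction
#'
#' Half-open intervals exactly as defined for the tile taxonomy:
#' 0: <5%, 1: >=5% and <33%, 2: >=33% and <66%, 3: >=66%.
#'
#' @param frac Area fraction in \[0, 1\].
#' @return Integer class 0-3 (vectorised).
#' @export
steatosis_class_from_fraction <- function(frac) {
  stopifnot(all(frac >= 0 & frac <= 1))
  as.integer((frac >= 0.05) + (frac >= 0.33) + (frac >= 0.66))
}
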