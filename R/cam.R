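# Class activation maps: M_c(x, y) = sum_k w_ck f_kxy over the backbone's
# final convolutional feature maps, with the identity
#   s_c = sum_k w_ck F_k = sum_{x,y} M_c(x, y) / (H W)
# (bias omitted). The classic CAM formulation uses a plain spatial sum for
# F_k; the pooling layer here is a true average, so the constant H*W is
# tracked explicitly and stored with the map to keep the identity exact.

# f_kxy tensor of one tile (post-ReLU last conv features), H x W x K.
feature_tensor <- function(model, tile) {
  if (inherits(tile, "synthetic_tile")) tile <- tile$image
  if (model$backbone == "inception_v3_contract") {
    return(model$backbone_fn(tile))
  }
  indices <- model_conv_indices(model)
  fw <- forward_reference(model, standardize_input(model, list(tile)), indices)
  array(fw$feat[, 1], dim = c(model$feat_h, model$feat_w, model$n_maps))
}

# Separable bilinear upscaling of a matrix to out_h x out_w.
bilinear_upscale <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  map_axis <- function(n_out, n_in) {
    # align centers: output pixel centres mapped into input coordinates
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pos <- pmin(pmax(pos, 1), n_in)
    lo <- pmin(floor(pos), n_in - 1L)
    if (n_in == 1L) lo <- rep(1L, n_out)
    list(lo = as.integer(lo), w = pos - lo)
  }
  ry <- map_axis(out_h, in_h); rx <- map_axis(out_w, in_w)
  hi_y <- pmin(ry$lo + 1L, in_h); hi_x <- pmin(rx$lo + 1L, in_w)
  wy <- matrix(ry$w, out_h, out_w)
  wx <- matrix(rx$w, out_h, out_w, byrow = TRUE)
  m00 <- m[ry$lo, rx$lo, drop = FALSE]
  m01 <- m[ry$lo, hi_x, drop = FALSE]
  m10 <- m[hi_y, rx$lo, drop = FALSE]
  m11 <- m[hi_y, hi_x, drop = FALSE]
  m00 * (1 - wy) * (1 - wx) + m01 * (1 - wy) * wx +
    m10 * wy * (1 - wx) + m11 * wy * wx
}

#' Compute the class activation map of a tile
#'
#' \eqn{M_c(x,y) = \sum_k w_{ck} f_{kxy}} at the feature resolution of
#' the backbone (9 x 9 for reference_small, 8 x 8 for the Inception-V3
#' contract), plus a bilinear upscaling to the 299 px tile. The dense
#' bias is omitted; the stored `pooling_constant` H*W links the map sum
#' to the pre-softmax class score: `sum(M) / pooling_constant = s_c`.
#'
#' @param model A trained (or untrained) `nash_cnn`.
#' @param tile 299 x 299 x 3 array or `synthetic_tile`.
#' @param class_index 0-based class index (the ignore class is
#'   `n_out - 1`).
#' @return An `activation_map` list: `M` (feature-resolution matrix),
#'   `upscaled` (299 x 299), `class_index`, `s_c` (pre-softmax score,
#'   bias omitted), `pooling_constant`, `probability` (softmax output for
#'   the class).
#' @export
compute_cam <- function(model, tile, class_index) {
  stopifnot(inherits(model, "nash_cnn"))
  if (class_index < 0 || class_index >= model$n_out) {
    stop(sprintf("class_index %d out of range 0..%d", class_index,
                 model$n_out - 1L), call. = FALSE)
  }
  f <- feature_tensor(model, tile)
  d <- dim(f)
  P <- d[1] * d[2]
  w_c <- model$dense$W[, class_index + 1L]
  M <- matrix(matrix(f, P, d[3]) %*% w_c, d[1], d[2])
  Fk <- colMeans(matrix(f, P, d[3]))
  s_c <- sum(Fk * w_c)
  logits <- as.numeric(Fk %*% model$dense$W + model$dense$b)
  prob <- exp(logits - max(logits)); prob <- prob / sum(prob)
  structure(list(M = M, upscaled = bilinear_upscale(M, 299L, 299L),
                 class_index = class_index, s_c = s_c,
                 pooling_constant = P,
                 probability = prob[class_index + 1L]),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> class %d: %dx%d grid, sum(M)/HW = %.5g, p = %.3f\n",
              x$class_index, nrow(x$M), ncol(x$M),
              sum(x$M) / x$pooling_constant, x$probability))
  invisible(x)
}

# 3x5 bitmap glyphs for the probability label.
cam_glyphs <- list(
  "0" = c(1,1,1, 1,0,1, 1,0,1, 1,0,1, 1,1,1),
  "1" = c(0,1,0, 1,1,0, 0,1,0, 0,1,0, 1,1,1),
  "2" = c(1,1,1, 0,0,1, 1,1,1, 1,0,0, 1,1,1),
  "3" = c(1,1,1, 0,0,1, 0,1,1, 0,0,1, 1,1,1),
  "4" = c(1,0,1, 1,0,1, 1,1,1, 0,0,1, 0,0,1),
  "5" = c(1,1,1, 1,0,0, 1,1,1, 0,0,1, 1,1,1),
  "6" = c(1,1,1, 1,0,0, 1,1,1, 1,0,1, 1,1,1),
  "7" = c(1,1,1, 0,0,1, 0,1,0, 0,1,0, 0,1,0),
  "8" = c(1,1,1, 1,0,1, 1,1,1, 1,0,1, 1,1,1),
  "9" = c(1,1,1, 1,0,1, 1,1,1, 0,0,1, 1,1,1),
  "." = c(0,0,0, 0,0,0, 0,0,0, 0,0,0, 0,1,0))

draw_label <- function(img, text, x0 = 8L, y0 = 8L, scale = 4L) {
  for (chr in strsplit(text, "")[[1]]) {
    glyph <- cam_glyphs[[chr]]
    if (!is.null(glyph)) {
      g <- matrix(glyph, 5, 3, byrow = TRUE)
      g <- g[rep(1:5, each = scale), rep(1:3, each = scale)]
      rr <- y0 + seq_len(nrow(g)) - 1L
      cc <- x0 + seq_len(ncol(g)) - 1L
      for (ch in 1:3) {
        sl <- img[rr, cc, ch]
        sl[g == 1] <- 1
        img[rr, cc, ch] <- sl
      }
    }
    x0 <- x0 + 4L * scale
  }
  img
}

#' Render an activation-map overlay
#'
#' Deterministic alpha blend of the tile with the colour-mapped upscaled
#' activation map; optionally prints the class output probability in the
#' top-left corner.
#'
#' @param tile 299 x 299 x 3 array or `synthetic_tile`.
#' @param cam An [compute_cam()] result (or any 299 x 299 matrix).
#' @param alpha Blend weight of the colour-mapped map (0 = tile only,
#'   1 = map only).
#' @param colormap Palette name passed to [grDevices::hcl.colors()]
#'   (default `"viridis"`).
#' @param probability If non-`NULL`, printed (2 decimals) in the corner;
#'   pass `cam$probability` for the standard annotation.
#' @return 299 x 299 x 3 RGB array.
#' @export
render_overlay <- function(tile, cam, alpha = 0.4, colormap = "viridis",
                           probability = NULL) {
  if (inherits(tile, "synthetic_tile")) tile <- tile$image
  m <- if (inherits(cam, "activation_map")) cam$upscaled else cam
  if (!all(dim(m) == dim(tile)[1:2])) {
    stop("activation map and tile sizes differ", call. = FALSE)
  }
  rng <- range(m)
  mn <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  pal <- grDevices::hcl.colors(256L, colormap)
  rgbm <- grDevices::col2rgb(pal[pmin(255L, floor(mn * 255)) + 1L]) / 255
  out <- tile
  for (ch in 1:3) {
    out[, , ch] <- (1 - alpha) * tile[, , ch] +
      alpha * matrix(rgbm[ch, ], nrow(m), ncol(m))
  }
  if (!is.null(probability)) {
    out <- draw_label(out, sprintf("%.2f", probability))
  }
  clamp01(out)
}

#' Write an activation map to disk
#'
#' The overlay as PNG and (optionally) the raw feature-resolution grid as
#' CSV.
#'
#' @param tile,cam,alpha,colormap As in [render_overlay()].
#' @param png_path Overlay PNG path.
#' @param csv_path Optional CSV path for the raw `M` grid.
#' @return `png_path`, invisibly.
#' @export
write_overlay_png <- function(tile, cam, png_path, csv_path = NULL,
                              alpha = 0.4, colormap = "viridis") {
  ov <- render_overlay(tile, cam, alpha, colormap,
                       probability = if (inherits(cam, "activation_map"))
                         cam$probability)
  png::writePNG(ov, png_path)
  if (!is.null(csv_path) && inherits(cam, "activation_map")) {
    utils::write.table(cam$M, csv_path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(png_path)
}
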