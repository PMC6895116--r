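# Two-scale non-overlapping tiling of whole-slide images.
#
# High-magnification tiles: 299 x 299 px source squares at 0.44 um/px,
# exported unmodified. Low-magnification tiles: 897 x 897 px source
# squares downscaled 1:3 (area mean) to 299 x 299 px at 1.32 um/px.
# Grids are axis-aligned, non-overlapping and 0-based; partial border
# tiles are dropped rather than padded, so a W x H image yields
# floor(W/s) * floor(H/s) tiles with s the source edge.

#' Compute the non-overlapping tile grid of an image
#'
#' @param image_width,image_height Image dimensions in pixels.
#' @param scale `"high"` (299 px source squares) or `"low"` (897 px source
#'   squares, downscaled 1:3 on extraction).
#' @param slide_id Identifier stored in the grid.
#' @return A `tile_grid`: data frame with columns `row`, `col` (0-based),
#'   `x0`, `y0` (top-left source pixel, 0-based) and attributes `scale`,
#'   `source_px`, `output_px`, `downscale`, `slide_id`.
#' @examples
#' nrow(grid_tiles(598, 598, "high"))   # 4
#' nrow(grid_tiles(897, 897, "low"))    # 1
#' @export
grid_tiles <- function(image_width, image_height, scale = c("high", "low"),
                       slide_id = "slide") {
  scale <- match.arg(scale)
  s <- if (scale == "low") 897L else 299L
  if (image_width < s || image_height < s) {
    stop(sprintf("image %dx%d smaller than one %s-scale tile (%d px)",
                 image_width, image_height, scale, s), call. = FALSE)
  }
  ncols <- floor(image_width / s)
  nrows <- floor(image_height / s)
  g <- expand.grid(col = seq_len(ncols) - 1L, row = seq_len(nrows) - 1L)
  g <- g[, c("row", "col")]
  g$x0 <- g$col * s
  g$y0 <- g$row * s
  rownames(g) <- NULL
  structure(g, scale = scale, source_px = s, output_px = 299L,
            downscale = if (scale == "low") 3L else 1L,
            slide_id = slide_id, class = c("tile_grid", "data.frame"))
}

# Exact 1:k area-mean (block mean) downscaling of an H x W x 3 array.
block_mean <- function(img, k) {
  d <- dim(img)
  stopifnot(d[1] %% k == 0, d[2] %% k == 0)
  h <- d[1] %/% k; w <- d[2] %/% k
  out <- array(0, dim = c(h, w, d[3]))
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    # average rows within blocks, then columns
    dim(m) <- c(k, h * d[2])
    m <- colMeans(m)
    dim(m) <- c(h, d[2])
    m <- t(m)
    dim(m) <- c(k, w * h)
    m <- colMeans(m)
    dim(m) <- c(w, h)
    out[, , ch] <- t(m)
  }
  out
}

#' Extract one tile from a slide image
#'
#' High scale returns the 299 x 299 crop unmodified; low scale crops the
#' 897 x 897 source square and downscales it 1:3 by exact 3 x 3 block
#' (area) averaging.
#'
#' @param image RGB array (H x W x 3, values in \[0, 1\]).
#' @param tile One row of a [grid_tiles()] grid (or a list with `x0`,
#'   `y0`).
#' @param scale `"high"` or `"low"`.
#' @return A 299 x 299 x 3 array.
#' @export
extract_tile <- function(image, tile, scale = c("high", "low")) {
  scale <- match.arg(scale)
  s <- if (scale == "low") 897L else 299L
  x0 <- tile$x0; y0 <- tile$y0
  d <- dim(image)
  if (x0 < 0 || y0 < 0 || x0 + s > d[2] || y0 + s > d[1]) {
    stop("tile out of image bounds", call. = FALSE)
  }
  crop <- image[y0 + seq_len(s), x0 + seq_len(s), , drop = FALSE]
  if (scale == "low") block_mean(crop, 3L) else crop
}

#' Read a slide image (TIFF/BigTIFF single plane, or PNG)
#'
#' The tool assumes slides exported at 0.44 um/px; `um_per_px` declares
#' the input resolution and anything off by more than 1% is rejected
#' rather than silently rescaled.
#'
#' @param path Image path (`.tif`, `.tiff`, `.png`).
#' @param um_per_px Declared input resolution (default 0.44).
#' @return RGB array (H x W x 3) in \[0, 1\].
#' @export
read_slide <- function(path, um_per_px = 0.44) {
  if (abs(um_per_px - 0.44) > 0.44 * 0.01) {
    stop(sprintf("input resolution %g um/px is not 0.44 within 1%%; rescaling unsupported",
                 um_per_px), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported slide format '.%s'", ext), call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Cut a slide into tiles on disk
#'
#' Writes each grid tile as PNG named `{slide_id}_{scale}_{row}_{col}.png`
#' plus a CSV manifest (`slide_id`, `scale`, `row`, `col`, `x0`, `y0`,
#' `file`).
#'
#' @param image RGB array or a slide path readable by [read_slide()].
#' @param scale `"high"` or `"low"`.
#' @param out_dir Output directory.
#' @param slide_id Slide identifier used in file names.
#' @return Invisibly, the manifest data frame.
#' @export
write_tiles <- function(image, scale, out_dir, slide_id = "slide") {
  if (is.character(image)) image <- read_slide(image)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(image)
  grid <- grid_tiles(d[2], d[1], scale, slide_id = slide_id)
  grid$file <- sprintf("%s_%s_%d_%d.png", slide_id, scale, grid$row, grid$col)
  for (i in seq_len(nrow(grid))) {
    t <- extract_tile(image, grid[i, ], scale)
    png::writePNG(t, file.path(out_dir, grid$file[i]))
  }
  manifest <- data.frame(slide_id = slide_id, scale = scale,
                         grid[, c("row", "col", "x0", "y0", "file")])
  utils::write.csv(manifest, file.path(out_dir, paste0(slide_id, "_manifest.csv")),
                   row.names = FALSE)
  invisible(manifest)
}
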