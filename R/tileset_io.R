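# Labeled tile sets on disk: one directory per class of PNG tiles, the
# layout consumed for classifier training.

#' Write a labeled tile set as class-named PNG folders
#'
#' @param tiles List of 299 x 299 x 3 arrays or `synthetic_tile` objects.
#' @param labels Class labels parallel to `tiles` (integers or
#'   `"ignore"`).
#' @param dir Root directory; one subdirectory per class is created.
#' @return Invisibly, the written file paths.
#' @export
write_tile_set <- function(tiles, labels, dir) {
  tiles <- as_tile_list(tiles)
  labels <- as.character(labels)
  stopifnot(length(tiles) == length(labels))
  paths <- character(length(tiles))
  counter <- list()
  for (i in seq_along(tiles)) {
    cl <- labels[i]
    sub <- file.path(dir, cl)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    counter[[cl]] <- (counter[[cl]] %||% 0L) + 1L
    paths[i] <- file.path(sub, sprintf("tile_%05d.png", counter[[cl]]))
    png::writePNG(tiles[[i]], paths[i])
  }
  invisible(paths)
}

#' Read a labeled tile set from class-named PNG folders
#'
#' @param dir Root directory whose subdirectories are class labels.
#' @return List with `tiles` (list of arrays) and `labels` (character).
#' @export
read_tile_set <- function(dir) {
  classes <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  if (length(classes) == 0L) stop("no class folders found", call. = FALSE)
  tiles <- list(); labels <- character()
  for (cl in classes) {
    files <- list.files(file.path(dir, cl), pattern = "\\.png$",
                        full.names = TRUE)
    for (f in files) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
      tiles[[length(tiles) + 1L]] <- img[, , 1:3, drop = FALSE]
      labels <- c(labels, cl)
    }
  }
  list(tiles = tiles, labels = labels)
}
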