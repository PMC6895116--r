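# From per-tile softmax confidences to one continuous score per liver.
#
# A tile's confidence vector q = (q_0 ... q_{C-2}, q_ignore) is kept only
# if ignore is not its argmax; kept vectors are renormalized over the
# non-ignore classes, p_j = q_j / sum_{i<=C-2} q_i, summarized as the
# weighted class <i p_i> = sum_i i p_i, and a liver's continuous score x
# is the arithmetic mean of its retained tiles' weighted classes.
#
# The weighted-class sum runs over the non-ignore classes 0 ... C-2 only:
# p is not defined for the ignore class, so its index never contributes.

as_conf_matrix <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  q <- as.matrix(q)
  if (any(q < -1e-9)) stop("negative confidences", call. = FALSE)
  if (any(abs(rowSums(q) - 1) > 1e-6)) {
    stop("confidence rows must sum to 1", call. = FALSE)
  }
  q
}

#' Drop ignore-dominated tiles
#'
#' Retains exactly the rows whose argmax is not the ignore class (last
#' column). Ties are broken toward the lowest index, so a tie between a
#' real class and ignore retains the tile.
#'
#' @param q Confidence matrix, one row per tile, ignore last.
#' @return List: `retained` (subset matrix), `keep` (logical vector).
#' @examples
#' filter_ignore(rbind(c(0.1, 0.2, 0.7), c(0.5, 0.2, 0.3)))$keep  # FALSE TRUE
#' @export
filter_ignore <- function(q) {
  q <- as_conf_matrix(q)
  keep <- max.col(q, ties.method = "first") != ncol(q)
  list(retained = q[keep, , drop = FALSE], keep = keep)
}

#' Renormalize confidences without the ignore class
#'
#' p_j = q_j / sum over the non-ignore classes of q, so p sums to 1.
#' Degenerate rows with zero non-ignore mass (impossible for retained
#' tiles) raise an error.
#'
#' @param q Confidence matrix or vector (ignore last).
#' @return Matrix with one column per non-ignore class.
#' @examples
#' renormalize(c(0.2, 0.3, 0.5))   # 0.4 0.6
#' @export
renormalize <- function(q) {
  q <- as_conf_matrix(q)
  p <- q[, -ncol(q), drop = FALSE]
  s <- rowSums(p)
  if (any(s <= 0)) stop("degenerate tile: zero non-ignore mass", call. = FALSE)
  p / s
}

#' Weighted average class score of a tile
#'
#' \eqn{\langle i p_i \rangle = \sum_i i\, p_i} over the non-ignore
#' classes 0 ... C-2.
#'
#' @param p Renormalized confidence matrix or vector (rows sum to 1).
#' @return Numeric vector, one weighted class per row, in \[0, C-2\].
#' @examples
#' weighted_class(c(0.4, 0.6))  # 0.6
#' @export
weighted_class <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    stop("renormalized rows must sum to 1", call. = FALSE)
  }
  as.numeric(p %*% (seq_len(ncol(p)) - 1))
}

#' Aggregate tile confidences into one continuous liver score
#'
#' Filters ignore-dominated tiles, renormalizes the rest, and averages
#' their weighted classes: \eqn{x = (1/N) \sum \langle i p_i \rangle}
#' over the N retained tiles.
#'
#' @param q Confidence matrix for all tiles of one liver (ignore last).
#' @param sample_id,feature Identifiers carried into the result.
#' @param min_retained Below this retained-tile count a warning flag is
#'   set (default 10).
#' @return A `liver_score` list: `sample_id`, `feature`, `x`,
#'   `n_tiles_total`, `n_tiles_retained`, `low_retention`.
#' @examples
#' aggregate_liver(rbind(c(1, 0, 0, 0), c(0, 0, 1, 0)))$x  # 1
#' @export
aggregate_liver <- function(q, sample_id = "sample", feature = NULL,
                            min_retained = 10L) {
  q <- as_conf_matrix(q)
  fi <- filter_ignore(q)
  n_ret <- nrow(fi$retained)
  if (n_ret == 0L) {
    stop(sprintf("no tissue: all %d tiles of '%s' are ignore-dominated",
                 nrow(q), sample_id), call. = FALSE)
  }
  x <- mean(weighted_class(renormalize(fi$retained)))
  structure(list(sample_id = sample_id, feature = feature, x = x,
                 n_tiles_total = nrow(q), n_tiles_retained = n_ret,
                 low_retention = n_ret < min_retained),
            class = "liver_score")
}

#' @export
print.liver_score <- function(x, ...) {
  cat(sprintf("<liver_score> %s%s: x = %.4f (%d/%d tiles retained%s)\n",
              x$sample_id,
              if (is.null(x$feature)) "" else paste0(" [", x$feature, "]"),
              x$x, x$n_tiles_retained, x$n_tiles_total,
              if (x$low_retention) ", LOW RETENTION" else ""))
  invisible(x)
}

#' Histogram of per-tile weighted class scores
#'
#' The tile-level score distribution underlying a liver's continuous
#' score (ignore-dominated tiles excluded).
#'
#' @param q Confidence matrix (ignore last).
#' @param bins Number of equal-width bins over \[0, C-2\].
#' @return Data frame: `mid` (bin midpoint), `count`; counts sum to the
#'   retained tile count.
#' @export
score_distribution <- function(q, bins = 40L) {
  fi <- filter_ignore(as_conf_matrix(q))
  if (nrow(fi$retained) == 0L) stop("no retained tiles", call. = FALSE)
  w <- weighted_class(renormalize(fi$retained))
  top <- ncol(fi$retained) - 2L
  breaks <- seq(0, top, length.out = bins + 1L)
  h <- hist(w, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  data.frame(mid = h$mids, count = h$counts)
}
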