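# Minimal convolutional network engine (im2col matrix convolutions).
#
# The classifier head is fixed across backbones: the backbone's
# last convolutional feature maps f_kxy are global-average-pooled to F_k,
# passed through dropout (rate 0.5) and one dense layer with weights w_ck,
# and normalised by softmax. The reference_small backbone is a three-layer
# convolutional stack sized to train on one CPU in minutes; an
# inception_v3_contract option accepts any user-supplied backbone function
# exposing an f_kxy tensor.
#
# All convolutions are expressed as gather (im2col) + matrix multiply so
# that base R BLAS does the heavy lifting; gradients are exact.

# Precompute the im2col gather index for one convolution.
conv_index <- function(in_h, in_w, in_c, k, stride) {
  out_h <- (in_h - k) %/% stride + 1L
  out_w <- (in_w - k) %/% stride + 1L
  # patch offsets (dr, dc, ch) relative to the patch origin, column-major
  dr <- rep(0:(k - 1L), times = k * in_c)
  dc <- rep(rep(0:(k - 1L), each = k), times = in_c)
  ch <- rep(0:(in_c - 1L), each = k * k)
  offsets <- dr + dc * in_h + ch * in_h * in_w
  or <- rep(seq_len(out_h) - 1L, times = out_w)
  oc <- rep(seq_len(out_w) - 1L, each = out_h)
  starts <- or * stride + oc * stride * in_h + 1L
  idx <- outer(starts, offsets, "+")
  storage.mode(idx) <- "integer"
  list(idx = idx, out_h = out_h, out_w = out_w, P = out_h * out_w,
       L = k * k * in_c)
}

he_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / nrow)), nrow, ncol)
}

REFERENCE_SMALL_LAYOUT <- list(
  list(k = 13L, stride = 13L, out = 16L),
  list(k = 3L,  stride = 2L,  out = 32L),
  list(k = 3L,  stride = 1L,  out = 48L)
)

#' Build an untrained per-feature tile classifier
#'
#' The head is global average pooling over the backbone's final
#' convolutional feature maps, dropout at rate 0.5, and a dense softmax
#' layer with one output per tile class including ignore (fibrosis 6,
#' ballooning 3, inflammation 4, steatosis 5).
#'
#' `reference_small` is a three-layer convolution stack (13x13/stride 13,
#' 3x3/stride 2, 3x3/stride 1; 16/32/48 maps; ReLU) over standardized
#' 299 x 299 RGB input, giving a 9 x 9 x 48 f_kxy tensor.
#' `inception_v3_contract` instead wraps any supplied `backbone_fn(tile)`
#' returning an H x W x K feature array (8 x 8 x 2048 for Inception-V3),
#' training only the head.
#'
#' @param feature A [feature_spec()] or feature name.
#' @param backbone `"reference_small"` or `"inception_v3_contract"`.
#' @param seed Integer seed for weight initialization.
#' @param backbone_fn Required for the contract backbone: function mapping
#'   a 299 x 299 x 3 array to an H x W x K feature array.
#' @param n_feature_maps K of the contract backbone (inferred from a probe
#'   call if omitted).
#' @return A `nash_cnn` model object.
#' @examples
#' m <- build_model("ballooning", seed = 1)
#' m$n_out   # 3
#' @export
build_model <- function(feature, backbone = "reference_small", seed = 1L,
                        backbone_fn = NULL, n_feature_maps = NULL) {
  spec <- if (inherits(feature, "feature_spec")) feature else feature_spec(feature)
  if (!backbone %in% c("reference_small", "inception_v3_contract")) {
    stop(sprintf("unknown backbone '%s'", backbone), call. = FALSE)
  }
  C <- spec$n_classes
  local_seed(seed, {
    if (backbone == "reference_small") {
      h <- 299L; w <- 299L; c_in <- 3L
      conv <- list()
      for (ly in REFERENCE_SMALL_LAYOUT) {
        ci <- conv_index(h, w, c_in, ly$k, ly$stride)
        conv[[length(conv) + 1L]] <- list(
          k = ly$k, stride = ly$stride, in_c = c_in, out_c = ly$out,
          in_h = h, in_w = w, out_h = ci$out_h, out_w = ci$out_w,
          W = he_init(ci$L, ly$out), b = numeric(ly$out))
        h <- ci$out_h; w <- ci$out_w; c_in <- ly$out
      }
      K <- c_in; fh <- h; fw <- w
    } else {
      if (is.null(backbone_fn)) {
        stop("inception_v3_contract requires backbone_fn", call. = FALSE)
      }
      if (is.null(n_feature_maps)) {
        probe <- backbone_fn(array(0, dim = c(299L, 299L, 3L)))
        fh <- dim(probe)[1]; fw <- dim(probe)[2]
        n_feature_maps <- dim(probe)[3]
      } else {
        fh <- fw <- NA_integer_
      }
      conv <- NULL
      K <- n_feature_maps
    }
    structure(list(
      feature = spec, backbone = backbone, backbone_fn = backbone_fn,
      conv = conv, feat_h = fh, feat_w = fw, n_maps = K, n_out = C,
      dense = list(W = he_init(K, C) * 0.5, b = numeric(C)),
      dropout_rate = 0.5, input_norm = c(mean = 0.5, sd = 0.25),
      seed = seed, trained = FALSE),
      class = "nash_cnn")
  })
}

#' @export
print.nash_cnn <- function(x, ...) {
  cat(sprintf("<nash_cnn> %s (%s), %d outputs incl. ignore%s\n",
              x$feature$feature, x$backbone, x$n_out,
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}

# Gather indices are derived from layer geometry; cached per model size.
model_conv_indices <- function(model) {
  lapply(model$conv, function(ly) {
    conv_index(ly$in_h, ly$in_w, ly$in_c, ly$k, ly$stride)
  })
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax_rows <- function(z) {
  z <- exp(z - apply(z, 1, max))
  z / rowSums(z)
}

# Forward pass over a batch. `x` is a (299*299*3) x N matrix of
# standardized images. Returns pooled features and (optionally) caches.
forward_reference <- function(model, x, indices, keep_cache = FALSE) {
  N <- ncol(x)
  caches <- if (keep_cache) vector("list", length(model$conv))
  cur <- x  # flattened activations, one column per image
  for (li in seq_along(model$conv)) {
    ly <- model$conv[[li]]
    ci <- indices[[li]]
    Xcol <- im2col_batch(cur, ci$idx)
    Z <- Xcol %*% ly$W
    Z <- Z + rep(ly$b, each = nrow(Z))
    A <- relu(Z)
    if (keep_cache) caches[[li]] <- list(Xcol = Xcol, mask = Z > 0)
    cur <- reflow_batch(A, ci$P)   # (out_h*out_w*out_c) x N
  }
  P <- model$feat_h * model$feat_w
  # GAP: F_k = mean_{x,y} f_kxy, per image
  Fmat <- t(matrix(colMeans(array(cur, dim = c(P, model$n_maps, N))),
                   model$n_maps, N))
  list(F = Fmat, feat = cur, caches = caches)
}

standardize_input <- function(model, imgs) {
  # imgs: list of H x W x 3 arrays -> flattened matrix, standardized
  x <- matrix(unlist(imgs, use.names = FALSE), ncol = length(imgs))
  (x - model$input_norm[["mean"]]) / model$input_norm[["sd"]]
}

pooled_features <- function(model, imgs, indices = NULL) {
  if (model$backbone == "inception_v3_contract") {
    Fmat <- t(vapply(imgs, function(im) {
      f <- model$backbone_fn(im)
      colMeans(matrix(f, prod(dim(f)[1:2]), dim(f)[3]))
    }, numeric(model$n_maps)))
    return(Fmat)
  }
  if (is.null(indices)) indices <- model_conv_indices(model)
  forward_reference(model, standardize_input(model, imgs), indices)$F
}

#' Predict tile confidence vectors
#'
#' Deterministic inference (dropout disabled). Output columns are ordered
#' class 0, 1, ... with ignore last; rows sum to 1.
#'
#' @param object A `nash_cnn` model.
#' @param tiles A list of 299 x 299 x 3 arrays, a single array, or a list
#'   of `synthetic_tile` objects.
#' @param ... Unused.
#' @return N x C matrix of softmax confidences.
#' @export
predict.nash_cnn <- function(object, tiles, ...) {
  tiles <- as_tile_list(tiles)
  bad <- vapply(tiles, function(t) !identical(dim(t)[1:2], c(299L, 299L)),
                TRUE)
  if (any(bad)) stop("tiles must be 299 x 299 RGB arrays", call. = FALSE)
  Fmat <- pooled_features(object, tiles)
  q <- softmax_rows(Fmat %*% object$dense$W +
                    rep(object$dense$b, each = nrow(Fmat)))
  colnames(q) <- class_labels(object$feature)
  q
}

as_tile_list <- function(tiles) {
  if (is.array(tiles) && length(dim(tiles)) == 3L) return(list(tiles))
  if (inherits(tiles, "synthetic_tile")) return(list(tiles$image))
  lapply(tiles, function(t) if (inherits(t, "synthetic_tile")) t$image else t)
}
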