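# Training: SGD with momentum, categorical cross-entropy, oversampling to
# class parity, on-the-fly augmentation, and reduce-on-plateau learning
# rate control monitored on a held-out validation split.

#' Training schedule
#'
#' Defaults are the fine-tuning regime this scoring approach was
#' developed with: SGD with initial
#' learning rate 0.5e-4 and momentum 0.9 minimising categorical
#' cross-entropy; when the validation loss fails to decrease for more than
#' two epochs the learning rate is multiplied by 0.2, floored at 1e-7;
#' class imbalance is equalised by oversampling; augmentation applies
#' rotations uniform in \[-pi/4, pi/4\], horizontal/vertical flips and
#' width/height shifts uniform in \[-30, 30\] px (reflection fill); ~90%
#' of tiles train, 10% validate. Batch size and epoch budget are not
#' pinned by the recipe and default to 32 and 50 with early stopping.
#'
#' Note the default learning rate assumes a pretrained backbone being
#' fine-tuned. Training the small reference backbone from random weights
#' needs a larger step; see the package vignette. Pass `initial_lr` to
#' override.
#'
#' @param initial_lr Initial learning rate.
#' @param momentum SGD momentum.
#' @param lr_factor Multiplier applied on plateau.
#' @param plateau_patience Epochs of non-decreasing validation loss
#'   tolerated before reduction (reduce on the `patience + 1`-th).
#' @param min_lr Learning-rate floor.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch budget.
#' @param early_stop_patience Non-improving epochs before stopping.
#' @param val_fraction Validation fraction of the labeled tiles.
#' @param stop_at_val_acc Optional early exit once the validation
#'   accuracy reaches this level (e.g. 0.97); `NULL` disables.
#' @param oversample Equalise class frequencies by oversampling.
#' @param augment Apply random augmentation to training tiles.
#' @param shift_px Maximal absolute shift in px.
#' @param max_rotation Maximal absolute rotation in radians.
#' @param clip_norm Global gradient-norm ceiling (stabilises from-scratch
#'   training at larger learning rates); `Inf` disables.
#' @return A `training_schedule` list.
#' @export
training_schedule <- function(initial_lr = 0.5e-4, momentum = 0.9,
                              lr_factor = 0.2, plateau_patience = 2L,
                              min_lr = 1e-7, batch_size = 32L,
                              max_epochs = 50L, early_stop_patience = 10L,
                              val_fraction = 0.1, stop_at_val_acc = NULL,
                              oversample = TRUE,
                              augment = TRUE, shift_px = 30,
                              max_rotation = pi / 4, clip_norm = 5) {
  structure(as.list(environment()), class = "training_schedule")
}

#' Learning-rate trace under the reduce-on-plateau rule
#'
#' Pure function of a validation-loss trace: the learning rate is
#' multiplied by `lr_factor` whenever the loss has failed to improve on
#' its running best for more than `plateau_patience` consecutive epochs,
#' and never drops below `min_lr`.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param schedule A [training_schedule()].
#' @return Numeric vector: the learning rate in effect at each epoch.
#' @export
plateau_lr_trace <- function(val_losses, schedule = training_schedule()) {
  lr <- schedule$initial_lr
  best <- Inf
  stall <- 0L
  out <- numeric(length(val_losses))
  for (e in seq_along(val_losses)) {
    out[e] <- lr
    if (val_losses[e] < best) {
      best <- val_losses[e]
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > schedule$plateau_patience) {
        lr <- max(lr * schedule$lr_factor, schedule$min_lr)
        stall <- 0L
      }
    }
  }
  out
}

#' Oversample class-imbalanced labels to parity
#'
#' Every class is sampled (with replacement for minority classes) up to
#' the majority-class count, so each epoch sees equal effective class
#' frequencies.
#'
#' @param labels Vector of class labels.
#' @return Integer index vector into `labels`, shuffled.
#' @export
oversample_indices <- function(labels) {
  tab <- table(labels)
  target <- max(tab)
  idx <- unlist(lapply(names(tab), function(cl) {
    pool <- which(labels == cl)
    if (length(pool) == target) pool
    else c(pool, sample(pool, target - length(pool), replace = TRUE))
  }), use.names = FALSE)
  sample(idx)
}

# Reflect 1-based coordinates into [1, n] (mirror-at-edge padding).
# Exact for one reflection period on each side, which covers every
# rotation/shift this package applies.
reflect_index <- function(i, n) {
  as.integer(n - 1L - abs((n - 1) - abs(i - 1))) + 1L
}

# Per-size cache of the centred target coordinate grids used by the
# augmentation resampler.
.aug_grid_cache <- new.env(parent = emptyenv())

aug_grid <- function(h, w) {
  key <- paste0(h, "x", w)
  g <- .aug_grid_cache[[key]]
  if (is.null(g)) {
    g <- list(r = rep(seq_len(h), times = w) - (h + 1) / 2,
              c = rep(seq_len(w), each = h) - (w + 1) / 2)
    .aug_grid_cache[[key]] <- g
  }
  g
}

# Linear source indices (single channel plane) for one augmentation draw.
augment_indices <- function(h, w, theta, flip_h, flip_v, dx, dy) {
  augment_indices_cpp(h, w, theta, flip_h, flip_v, dx, dy)
}

# Plain-R reference of the same resampler, kept as the test oracle for
# the compiled version.
augment_indices_ref <- function(h, w, theta, flip_h, flip_v, dx, dy) {
  g <- aug_grid(h, w)
  ca <- cos(-theta); sa <- sin(-theta)
  src_r <- reflect_index(round((h + 1) / 2 + sa * g$c + ca * g$r - dy), h)
  src_c <- reflect_index(round((w + 1) / 2 + ca * g$c - sa * g$r - dx), w)
  if (flip_v) src_r <- h + 1L - src_r
  if (flip_h) src_c <- w + 1L - src_c
  src_r + (src_c - 1L) * h
}

#' Randomly augment a tile (rotation, flips, shift; reflection fill)
#'
#' One nearest-neighbour resampling implementing flips, then rotation
#' about the tile centre, then translation, with out-of-range source
#' coordinates reflected at the borders.
#'
#' @param img H x W x 3 array.
#' @param theta Rotation in radians.
#' @param flip_h,flip_v Horizontal/vertical flips.
#' @param dx,dy Shift in px (width/height).
#' @return Augmented array of the same shape.
#' @export
augment_tile <- function(img, theta = 0, flip_h = FALSE, flip_v = FALSE,
                         dx = 0, dy = 0) {
  d <- dim(img)
  lin <- augment_indices(d[1], d[2], theta, flip_h, flip_v, dx, dy)
  np <- d[1] * d[2]
  lin3 <- c(lin, lin + np, lin + 2L * np)
  array(img[lin3], dim = d)
}

random_augment_params <- function(schedule) {
  list(theta = stats::runif(1, -schedule$max_rotation, schedule$max_rotation),
       flip_h = stats::runif(1) < 0.5,
       flip_v = stats::runif(1) < 0.5,
       dx = round(stats::runif(1, -schedule$shift_px, schedule$shift_px)),
       dy = round(stats::runif(1, -schedule$shift_px, schedule$shift_px)))
}

# Assemble a standardized training batch, augmenting in the gather.
make_batch <- function(model, tiles, schedule, augment) {
  n <- length(tiles)
  d <- dim(tiles[[1]])
  np <- d[1] * d[2]
  xb <- matrix(0, np * 3L, n)
  mu <- model$input_norm[["mean"]]; sdv <- model$input_norm[["sd"]]
  for (i in seq_len(n)) {
    img <- tiles[[i]]
    if (augment) {
      p <- random_augment_params(schedule)
      lin <- augment_indices(d[1], d[2], p$theta, p$flip_h, p$flip_v,
                             p$dx, p$dy)
      xb[, i] <- augment_gather(img, lin, np, mu, sdv)
    } else {
      xb[, i] <- (as.vector(img) - mu) / sdv
    }
  }
  xb
}

# One SGD step on a standardized batch. Returns updated model/velocity
# and the batch loss. y: integer class indices (1-based columns).
sgd_step <- function(model, vel, xb, y, lr, momentum, indices, dropout,
                     clip_norm = Inf) {
  N <- ncol(xb)
  fw <- forward_reference(model, xb, indices, keep_cache = TRUE)
  Fmat <- fw$F
  if (dropout > 0) {
    mask <- matrix(stats::runif(length(Fmat)) >= dropout, nrow(Fmat),
                   ncol(Fmat)) / (1 - dropout)
    Fd <- Fmat * mask
  } else {
    mask <- NULL
    Fd <- Fmat
  }
  logits <- Fd %*% model$dense$W + rep(model$dense$b, each = N)
  p <- softmax_rows(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(N), y)], 1e-12)))
  dlog <- p
  dlog[cbind(seq_len(N), y)] <- dlog[cbind(seq_len(N), y)] - 1
  dlog <- dlog / N
  grads <- list(dense_W = crossprod(Fd, dlog), dense_b = colSums(dlog))
  dF <- dlog %*% t(model$dense$W)
  if (!is.null(mask)) dF <- dF * mask
  # GAP backward: spread evenly over spatial positions
  P <- model$feat_h * model$feat_w
  nl <- length(model$conv)
  dcur <- matrix(rep(t(dF) / P, each = P), P * model$n_maps, N)
  for (li in nl:1) {
    ly <- model$conv[[li]]
    ci <- indices[[li]]
    cache <- fw$caches[[li]]
    dZ <- unflow_batch(dcur, ci$P) * cache$mask
    grads[[paste0("conv", li, "_W")]] <- crossprod(cache$Xcol, dZ)
    grads[[paste0("conv", li, "_b")]] <- colSums(dZ)
    if (li > 1L) {
      dXcol <- dZ %*% t(ly$W)
      dcur <- col2im_batch(dXcol, ci$idx, ly$in_h * ly$in_w * ly$in_c)
    }
  }
  if (is.finite(clip_norm)) {
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
    if (gnorm > clip_norm) {
      grads <- lapply(grads, function(g) g * (clip_norm / gnorm))
    }
  }
  # momentum update
  upd <- function(wname, vname, g) {
    vel[[vname]] <<- momentum * vel[[vname]] - lr * g
    vel[[vname]]
  }
  for (li in seq_along(model$conv)) {
    model$conv[[li]]$W <- model$conv[[li]]$W +
      upd("W", paste0("conv", li, "_W"), grads[[paste0("conv", li, "_W")]])
    model$conv[[li]]$b <- model$conv[[li]]$b +
      upd("b", paste0("conv", li, "_b"), grads[[paste0("conv", li, "_b")]])
  }
  model$dense$W <- model$dense$W + upd("W", "dense_W", grads$dense_W)
  model$dense$b <- model$dense$b + upd("b", "dense_b", grads$dense_b)
  list(model = model, vel = vel, loss = loss)
}

eval_split <- function(model, xmat, y, indices, batch = 64L) {
  N <- ncol(xmat)
  loss <- 0; correct <- 0L
  for (b0 in seq(1L, N, by = batch)) {
    cols <- b0:min(b0 + batch - 1L, N)
    Fmat <- forward_reference(model, xmat[, cols, drop = FALSE], indices)$F
    p <- softmax_rows(Fmat %*% model$dense$W +
                      rep(model$dense$b, each = length(cols)))
    loss <- loss - sum(log(pmax(p[cbind(seq_along(cols), y[cols])], 1e-12)))
    correct <- correct + sum(max.col(p) == y[cols])
  }
  c(loss = loss / N, acc = correct / N)
}

#' Train a tile classifier
#'
#' Splits the labeled tiles ~90/10 into train/validation (stratified),
#' oversamples minority classes to parity each epoch, augments training
#' tiles on the fly, and runs SGD with momentum under the
#' reduce-on-plateau learning-rate rule monitored on validation loss.
#' Fully seeded and reproducible.
#'
#' @param model An untrained [build_model()] result (reference_small
#'   backbone).
#' @param tiles List of 299 x 299 x 3 arrays or `synthetic_tile` objects.
#' @param labels Vector of class labels (integers or `"ignore"`),
#'   parallel to `tiles`.
#' @param schedule A [training_schedule()].
#' @param seed Integer seed.
#' @param verbose Print per-epoch progress.
#' @return The trained model, with `$history` (epoch, lr, train_loss,
#'   train_acc, val_loss, val_acc).
#' @export
train <- function(model, tiles, labels, schedule = training_schedule(),
                  seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "nash_cnn"))
  if (model$backbone != "reference_small") {
    stop("train() supports the reference_small backbone", call. = FALSE)
  }
  tiles <- as_tile_list(tiles)
  labels <- as.character(labels)
  stopifnot(length(tiles) == length(labels))
  classes <- class_labels(model$feature)
  if (!all(labels %in% classes)) stop("labels outside the feature's classes",
                                      call. = FALSE)
  if (length(unique(labels)) < 2L) stop("need >= 2 classes to train",
                                        call. = FALSE)
  y_all <- match(labels, classes)
  indices <- model_conv_indices(model)
  local_seed(seed, {
    # stratified ~90/10 split
    val_idx <- unlist(lapply(unique(labels), function(cl) {
      pool <- which(labels == cl)
      nv <- max(1L, round(length(pool) * schedule$val_fraction))
      sample(pool, nv)
    }), use.names = FALSE)
    if (length(val_idx) == 0L || length(val_idx) == length(tiles)) {
      stop("empty train or validation split", call. = FALSE)
    }
    tr_idx <- setdiff(seq_along(tiles), val_idx)
    xval <- standardize_input(model, tiles[val_idx])
    yval <- y_all[val_idx]
    vel <- list()
    for (li in seq_along(model$conv)) {
      vel[[paste0("conv", li, "_W")]] <- model$conv[[li]]$W * 0
      vel[[paste0("conv", li, "_b")]] <- model$conv[[li]]$b * 0
    }
    vel$dense_W <- model$dense$W * 0
    vel$dense_b <- model$dense$b * 0
    lr <- schedule$initial_lr
    best_val <- Inf; stall <- 0L; stop_stall <- 0L
    hist <- NULL
    for (epoch in seq_len(schedule$max_epochs)) {
      order_idx <- if (schedule$oversample) {
        tr_idx[oversample_indices(labels[tr_idx])]
      } else sample(tr_idx)
      ep_loss <- 0; ep_n <- 0L; ep_correct <- 0L
      for (b0 in seq(1L, length(order_idx), by = schedule$batch_size)) {
        bidx <- order_idx[b0:min(b0 + schedule$batch_size - 1L,
                                 length(order_idx))]
        xb <- make_batch(model, tiles[bidx], schedule, schedule$augment)
        st <- sgd_step(model, vel, xb, y_all[bidx], lr, schedule$momentum,
                       indices, model$dropout_rate, schedule$clip_norm)
        model <- st$model; vel <- st$vel
        ep_loss <- ep_loss + st$loss * length(bidx)
        ep_n <- ep_n + length(bidx)
      }
      ev <- eval_split(model, xval, yval, indices)
      hist <- rbind(hist, data.frame(
        epoch = epoch, lr = lr, train_loss = ep_loss / ep_n,
        val_loss = ev["loss"], val_acc = ev["acc"]))
      if (verbose) {
        message(sprintf("epoch %02d lr %.2g train %.4f val %.4f acc %.3f",
                        epoch, lr, ep_loss / ep_n, ev["loss"], ev["acc"]))
      }
      if (!is.null(schedule$stop_at_val_acc) &&
          ev["acc"] >= schedule$stop_at_val_acc) break
      if (ev["loss"] < best_val) {
        best_val <- ev["loss"]; stall <- 0L; stop_stall <- 0L
      } else {
        stall <- stall + 1L; stop_stall <- stop_stall + 1L
        if (stall > schedule$plateau_patience) {
          lr <- max(lr * schedule$lr_factor, schedule$min_lr)
          stall <- 0L
        }
        if (stop_stall >= schedule$early_stop_patience) break
      }
    }
    rownames(hist) <- NULL
    model$history <- hist
    model$trained <- TRUE
    model$train_seed <- seed
    model
  })
}

#' Save / load a model checkpoint
#'
#' One-file serialized checkpoint carrying the weights plus an embedded
#' JSON metadata block (feature, class order, scale, backbone, seed).
#'
#' @param model A `nash_cnn`.
#' @param path Destination file.
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: the
#'   model.
#' @export
save_checkpoint <- function(model, path) {
  meta <- jsonlite::toJSON(list(
    feature = model$feature$feature, classes = class_labels(model$feature),
    scale = model$feature$scale, backbone = model$backbone,
    seed = model$seed, trained = model$trained), auto_unbox = TRUE)
  obj <- list(meta = as.character(meta), model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), !is.null(obj$model))
  obj$model
}
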