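# Synthetic trichrome-like tile generator.
#
# Tiles are geometric caricatures of Masson's-trichrome liver histology:
# a red/purple tissue background, white lipid vacuoles (steatosis), pale
# enlarged rimmed cells (ballooning), dark small-cell clusters/disseminated
# dots (inflammation) and blue/violet collagen strands, bridges and nodules
# (fibrosis). The drawn geometry satisfies the tile-class definitions used
# for classifier training, so generated tiles come with exact ground truth.
# Appearance is deliberately schematic, not photorealistic: everything
# downstream of the classifier consumes only confidences and labels.
#
# Painting mutates a canvas environment in place; a 299 px tile costs a
# few milliseconds, which keeps property tests over hundreds of tiles
# cheap.

TILE_PX <- 299L

# Run code under a fixed seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# --- canvas: an environment holding the H x W x 3 raster ----------------

new_canvas <- function(px = TILE_PX, color = c(0.82, 0.52, 0.58),
                       noise = 0.035) {
  cv <- new.env(parent = emptyenv())
  cv$img <- array(rep(color, each = px * px), dim = c(px, px, 3)) +
    array(rnorm(px * px, 0, noise), dim = c(px, px, 3))
  cv$px <- px
  cv$shapes <- list()
  cv
}

# Composite all pending shapes onto the raster in one pass. Painting is
# deferred so the (large) raster is copied once per flush, not once per
# shape; within this scope R updates it in place.
flush_canvas <- function(cv) {
  if (length(cv$shapes) == 0L) return(invisible(NULL))
  img <- cv$img
  for (s in cv$shapes) {
    for (ch in 1:3) {
      sl <- img[s$rows, s$cols, ch]
      sl[s$mask] <- (1 - s$alpha) * sl[s$mask] + s$alpha * s$color[ch]
      img[s$rows, s$cols, ch] <- sl
    }
  }
  cv$img <- img
  cv$shapes <- list()
  invisible(NULL)
}

# Mask of a (super)ellipse restricted to its in-canvas bounding box.
# `expo` = 2 is an ellipse; higher even exponents give rounded squares.
shape_mask <- function(px, cx, cy, rx, ry, angle = 0, expo = 2) {
  r0 <- max(1L, floor(cy - max(rx, ry))); r1 <- min(px, ceiling(cy + max(rx, ry)))
  c0 <- max(1L, floor(cx - max(rx, ry))); c1 <- min(px, ceiling(cx + max(rx, ry)))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  ca <- cos(angle); sa <- sin(angle)
  u <- (dx * ca + dy * sa) / rx
  v <- (-dx * sa + dy * ca) / ry
  m <- if (expo == 2) (u * u + v * v) <= 1 else
    (abs(u)^expo + abs(v)^expo) <= 1
  list(mask = m, rows = rows, cols = cols, bbox = c(r0, r1, c0, c1))
}

apply_mask <- function(cv, sm, color, alpha = 1) {
  if (is.null(sm)) return(invisible(NULL))
  cv$shapes[[length(cv$shapes) + 1L]] <-
    list(rows = sm$rows, cols = sm$cols, mask = sm$mask, color = color,
         alpha = alpha)
  invisible(NULL)
}

paint_ellipse <- function(cv, cx, cy, rx, ry, angle, color, alpha = 1,
                          expo = 2) {
  sm <- shape_mask(cv$px, cx, cy, rx, ry, angle, expo)
  apply_mask(cv, sm, color, alpha)
  invisible(sm)
}

# Thick line segment (capsule shape).
paint_segment <- function(cv, x0, y0, x1, y1, width, color, alpha = 1) {
  px <- cv$px
  h <- width / 2 + 1
  r0 <- max(1L, floor(min(y0, y1) - h)); r1 <- min(px, ceiling(max(y0, y1) + h))
  c0 <- max(1L, floor(min(x0, x1) - h)); c1 <- min(px, ceiling(max(x0, x1) + h))
  if (r0 > r1 || c0 > c1) return(invisible(NULL))
  rows <- r0:r1; cols <- c0:c1
  Y <- outer(rows, rep(1, length(cols)))
  X <- outer(rep(1, length(rows)), cols)
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx * vx + vy * vy
  t <- if (L2 == 0) 0 else pmin(pmax(((X - x0) * vx + (Y - y0) * vy) / L2, 0), 1)
  d2 <- (X - (x0 + t * vx))^2 + (Y - (y0 + t * vy))^2
  apply_mask(cv, list(mask = d2 <= (width / 2)^2, rows = rows, cols = cols),
             color, alpha)
}

# Small dark nuclei speckle shared by all tissue tiles.
sprinkle_nuclei <- function(cv, n = 110) {
  px <- cv$px
  for (i in seq_len(n)) {
    paint_ellipse(cv, runif(1, 4, px - 4), runif(1, 4, px - 4),
                  runif(1, 1.6, 2.0), runif(1, 1.6, 2.0),
                  runif(1, 0, pi), c(0.45, 0.2, 0.35), alpha = 0.8)
  }
  invisible(NULL)
}

# --- per-feature tile painters ------------------------------------------

# Steatosis: white vacuoles until the pixel-counted area fraction reaches
# a target drawn inside the class interval (0: <5%, 1: [5,33)%,
# 2: [33,66)%, 3: >=66%). Vacuoles never touch (>= 3 px tissue gap) and
# each stays inside the CV labeler's size/roundness window, so classical
# segmentation can recover the drawn fraction. Low classes use scattered
# circles; high classes use a jittered grid of rounded-square vacuoles,
# the packed-vacuole morphology of severe steatosis. The union mask is
# tracked, so the achieved fraction is pixel-exact.
draw_steatosis <- function(cv, cls) {
  px <- cv$px; npix <- px * px
  bounds <- list(`0` = c(0.008, 0.040), `1` = c(0.07, 0.28),
                 `2` = c(0.36, 0.58), `3` = c(0.663, 0.72))
  b <- bounds[[as.character(cls)]]
  target <- runif(1, b[1], b[2])
  upper <- c(0.05, 0.33, 0.66, 1.00)[cls + 1]
  mask <- matrix(FALSE, px, px)
  frac <- 0
  vac_col <- c(0.965, 0.955, 0.96)
  add_shape <- function(cx, cy, rx, ry, expo) {
    # accept only if the 3-px-dilated footprint avoids earlier vacuoles
    probe <- shape_mask(px, cx, cy, rx + 3, ry + 3, 0, expo)
    if (is.null(probe)) return(FALSE)
    if (any(mask[probe$rows, probe$cols] & probe$mask)) return(FALSE)
    sm <- shape_mask(px, cx, cy, rx, ry, 0, expo)
    sub <- mask[sm$rows, sm$cols]
    newly <- sum(sm$mask & !sub)
    if (frac + newly / npix >= upper * 0.995) return(FALSE)
    apply_mask(cv, sm, vac_col)
    mask[sm$rows, sm$cols] <<- sub | sm$mask
    frac <<- frac + newly / npix
    TRUE
  }
  if (cls <= 1L) {
    rlim <- if (cls == 0L) c(5, 12) else c(7, 16)
    guard <- 0L
    while (frac < target && guard < 3000L) {
      guard <- guard + 1L
      r <- runif(1, rlim[1], rlim[2])
      add_shape(runif(1, r + 2, px - r - 2), runif(1, r + 2, px - r - 2),
                r, r * runif(1, 0.9, 1.1), expo = 2)
    }
  } else {
    cell <- 40
    half <- 17.5  # half-width; 2 * (cell/2 - half - jitter) >= 3 px gap
    cx0 <- runif(1, 8, 12); cy0 <- runif(1, 8, 12)
    centers <- expand.grid(cx = seq(cx0, px + 10, by = cell),
                           cy = seq(cy0, px + 10, by = cell))
    centers <- centers[sample(nrow(centers)), ]
    for (i in seq_len(nrow(centers))) {
      if (frac >= target) break
      add_shape(centers$cx[i] + runif(1, -1, 1),
                centers$cy[i] + runif(1, -1, 1),
                half + runif(1, -1.5, 0), half + runif(1, -1.5, 0),
                expo = 4)
    }
    # fill gaps with small circles if the grid alone fell short
    guard <- 0L
    while (frac < target && guard < 3000L) {
      guard <- guard + 1L
      r <- runif(1, 4.5, 8)
      add_shape(runif(1, r + 2, px - r - 2), runif(1, r + 2, px - r - 2),
                r, r, expo = 2)
    }
  }
  list(area_fraction = frac, target_fraction = target, vacuole_mask = mask)
}

# Ballooning: class 1 has >= 1 enlarged pale cell with a visible rim.
draw_ballooning <- function(cv, cls) {
  n_cells <- if (cls == 0) 0L else sample(1:3, 1)
  centers <- NULL
  px <- cv$px
  for (i in seq_len(n_cells)) {
    cx <- runif(1, 45, px - 45); cy <- runif(1, 45, px - 45)
    r <- runif(1, 26, 38)
    paint_ellipse(cv, cx, cy, r + 3, r + 3, 0, c(0.35, 0.22, 0.4))
    paint_ellipse(cv, cx, cy, r, r, 0, c(0.93, 0.88, 0.9))
    paint_ellipse(cv, cx + r / 3, cy - r / 4, 3.5, 3.5, 0, c(0.3, 0.15, 0.3))
    centers <- rbind(centers, c(cx, cy, r))
  }
  list(n_balloon_cells = n_cells, cells = centers)
}

# Inflammation: dark-cell clusters and disseminated dots.
# class 0: clusters < 3 cells and < 5 disseminated; class 1: clusters of
# 3-5 and/or 5-10 disseminated; class 2: clusters > 5 and/or > 10
# disseminated. (The printed class-0/1 boundary overlaps at exactly 5
# disseminated cells; resolved half-open: class 0 strictly < 5, class 1
# includes 5.)
draw_inflammation <- function(cv, cls) {
  px <- cv$px
  spec <- switch(as.character(cls),
    `0` = list(cluster = sample(0:2, 1), diss = sample(0:4, 1)),
    `1` = list(cluster = sample(3:5, 1), diss = sample(5:10, 1)),
    `2` = list(cluster = sample(6:12, 1), diss = sample(11:22, 1)))
  # lymphocyte-like cells: ~7 um across at 0.44 um/px, nearly uniform size
  dot <- function(x, y) {
    paint_ellipse(cv, x, y, runif(1, 3.8, 4.2), runif(1, 3.8, 4.2),
                  0, c(0.16, 0.1, 0.32))
  }
  if (spec$cluster > 0) {
    ccx <- runif(1, 40, px - 40); ccy <- runif(1, 40, px - 40)
    # cells arranged around the focus without overlapping each other
    ang <- runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = spec$cluster + 1)
    rad <- 10 + 9 * (seq_len(spec$cluster) %% 2)
    for (i in seq_len(spec$cluster)) {
      dot(ccx + rad[i] * cos(ang[i]) + runif(1, -1, 1),
          ccy + rad[i] * sin(ang[i]) + runif(1, -1, 1))
    }
  }
  for (i in seq_len(spec$diss)) dot(runif(1, 8, px - 8), runif(1, 8, px - 8))
  list(cluster_cells = spec$cluster, disseminated = spec$diss)
}

# Fibrosis: blue/violet collagen with class-specific topology.
draw_fibrosis <- function(cv, cls) {
  px <- cv$px
  col <- c(0.32, 0.38, 0.78)
  strands_at <- function(cx, cy, n, len, wd) {
    for (i in seq_len(n)) {
      a <- runif(1, 0, 2 * pi)
      x0 <- cx + runif(1, -8, 8); y0 <- cy + runif(1, -8, 8)
      paint_segment(cv, x0, y0, x0 + len * cos(a), y0 + len * sin(a),
                    wd, col, alpha = 0.9)
    }
  }
  params <- list(topology = cls)
  if (cls == 1) {
    # thin strands around a single (periportal-like) region
    cx <- runif(1, 60, px - 60); cy <- runif(1, 60, px - 60)
    paint_ellipse(cv, cx, cy, 9, 9, 0, c(0.9, 0.85, 0.9))
    strands_at(cx, cy, sample(3:5, 1), runif(1, 30, 55), 3)
    params$regions <- 1L
  } else if (cls == 2) {
    # strands at periportal AND perisinusoidal-like positions
    cx <- runif(1, 50, px / 2); cy <- runif(1, 50, px - 50)
    paint_ellipse(cv, cx, cy, 9, 9, 0, c(0.9, 0.85, 0.9))
    strands_at(cx, cy, sample(3:5, 1), runif(1, 30, 55), 3)
    for (i in seq_len(sample(10:16, 1))) {
      x0 <- runif(1, px / 2, px - 10); y0 <- runif(1, 10, px - 10)
      a <- runif(1, 0, 2 * pi)
      paint_segment(cv, x0, y0, x0 + 26 * cos(a), y0 + 26 * sin(a),
                    2.4, col, alpha = 0.85)
    }
    params$regions <- 2L
  } else if (cls == 3) {
    # bridging: a thick band connecting two node structures
    n1 <- c(runif(1, 40, 90), runif(1, 40, 90))
    n2 <- c(runif(1, px - 90, px - 40), runif(1, px - 90, px - 40))
    paint_ellipse(cv, n1[1], n1[2], 16, 16, 0, col)
    paint_ellipse(cv, n2[1], n2[2], 16, 16, 0, col)
    mid <- (n1 + n2) / 2 + rnorm(2, 0, 15)
    paint_segment(cv, n1[1], n1[2], mid[1], mid[2], 9, col)
    paint_segment(cv, mid[1], mid[2], n2[1], n2[2], 9, col)
    params$nodes <- rbind(n1, n2)
  } else if (cls == 4) {
    # cirrhosis: nodule fully enclosed by a collagen band (annulus)
    cx <- runif(1, 110, px - 110); cy <- runif(1, 110, px - 110)
    r <- runif(1, 55, 85)
    theta <- seq(0, 2 * pi, length.out = 36)
    for (i in seq_len(35)) {
      paint_segment(cv, cx + r * cos(theta[i]), cy + r * sin(theta[i]),
                    cx + r * cos(theta[i + 1]), cy + r * sin(theta[i + 1]),
                    8, col)
    }
    params$nodule <- c(cx, cy, r)
  }
  params
}

# Ignore tiles: mostly-empty border, blur-like washout, or a blood blob.
draw_ignore <- function(cv) {
  px <- cv$px
  kind <- sample(c("empty", "blur", "blood"), 1)
  flush_canvas(cv)  # whole-raster writes below must land on top
  if (kind == "empty") {
    cut <- sample(round(px * c(0.55, 0.65, 0.75)), 1)
    side <- sample(1:2, 1)
    white <- 0.975 + rnorm(cut * px, 0, 0.008)
    for (ch in 1:3) {
      if (side == 1) cv$img[1:cut, , ch] <- white
      else cv$img[, 1:cut, ch] <- white
    }
  } else if (kind == "blur") {
    # out of focus in bright field: texture gone, colours washed toward
    # the bright illumination background
    base <- colMeans(matrix(cv$img, ncol = 3))
    wash <- runif(1, 0.35, 0.55)
    for (ch in 1:3) {
      cv$img[, , ch] <- (1 - wash) * base[ch] + wash * 0.97 +
        matrix(rnorm(px * px, 0, 0.004), px, px)
    }
  } else {
    paint_ellipse(cv, px / 2 + rnorm(1, 0, 20), px / 2 + rnorm(1, 0, 20),
                  runif(1, 110, 150), runif(1, 110, 150),
                  runif(1, 0, pi), c(0.72, 0.08, 0.1))
  }
  list(ignore_kind = kind)
}

#' Generate one synthetic histology tile
#'
#' Draws a 299 x 299 RGB tile whose content satisfies the tile-class
#' definition for the requested feature: steatosis tiles carry white
#' vacuoles with a pixel-exact area fraction inside the class interval,
#' ballooning class 1 carries at least one enlarged pale rimmed cell,
#' inflammation tiles carry cluster/disseminated dark-cell counts inside
#' the class bounds, fibrosis tiles carry blue collagen with the staged
#' topology (single-region strands, both region types, a bridging band
#' between two nodes, or a fully enclosed nodule), and ignore tiles show
#' mostly empty space, blur, or a blood-dominant blob.
#'
#' @param feature A [feature_spec()] or feature name.
#' @param true_class Integer class label valid for the feature, or
#'   `"ignore"`.
#' @param seed Integer seed; tiles are bit-reproducible given
#'   (feature, class, seed).
#' @param params Optional list of overrides, currently `background_color`
#'   and `n_nuclei`.
#' @return A `synthetic_tile` list: `image` (299 x 299 x 3 array in
#'   \[0, 1\]), `feature`, `true_class`, `generator_params`, `seed`.
#' @examples
#' t0 <- generate_tile_image("steatosis", 2, seed = 1)
#' t0$generator_params$area_fraction   # inside [0.33, 0.66)
#' @export
generate_tile_image <- function(feature, true_class, seed = 1L,
                                params = list()) {
  spec <- if (inherits(feature, "feature_spec")) feature else feature_spec(feature)
  idx <- resolve_class(spec, true_class)  # validates the label
  local_seed(seed * 17L + idx, {
    cv <- new_canvas(color = params$background_color %||% c(0.82, 0.52, 0.58))
    sprinkle_nuclei(cv, n = params$n_nuclei %||% 110L)
    gp <- if (idx == spec$ignore_index) {
      draw_ignore(cv)
    } else {
      switch(spec$feature,
        steatosis    = draw_steatosis(cv, idx),
        ballooning   = draw_ballooning(cv, idx),
        inflammation = draw_inflammation(cv, idx),
        fibrosis     = draw_fibrosis(cv, idx))
    }
    flush_canvas(cv)
    structure(list(image = clamp01(cv$img), feature = spec$feature,
                   true_class = true_class, generator_params = gp,
                   seed = seed),
              class = "synthetic_tile")
  })
}

#' Generate a synthetic whole-slide image from a layout of tile classes
#'
#' Stitches independently generated tiles into one image so the tiling
#' module can be exercised end to end. For high-scale features the
#' stitched image is the tile mosaic itself (each grid cell 299 px). For
#' the low-scale fibrosis feature each 299 px tile is pixel-replicated 3x
#' to its 897 px source footprint, so that 1:3 area-mean downscaling
#' during tile extraction recovers each generated tile exactly.
#'
#' @param layout Matrix (or vector) of class labels (integers or
#'   `"ignore"`), one entry per tile position.
#' @param feature A [feature_spec()] or feature name.
#' @param seed Integer seed.
#' @return List with `image` (stitched RGB array), `labels` (the layout
#'   matrix), `feature`, and `tile_seeds` (matrix of per-tile seeds).
#' @export
generate_wsi <- function(layout, feature, seed = 1L) {
  spec <- if (inherits(feature, "feature_spec")) feature else feature_spec(feature)
  if (!is.matrix(layout)) layout <- matrix(layout, nrow = 1)
  nr <- nrow(layout); nc <- ncol(layout)
  stopifnot(nr >= 1, nc >= 1)
  s <- spec$source_px
  img <- array(0, dim = c(nr * s, nc * s, 3))
  tile_seeds <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      ts <- seed + 1000L * r + cc
      tile_seeds[r, cc] <- ts
      t <- generate_tile_image(spec, layout[r, cc], seed = ts)$image
      if (spec$downscale > 1L) {
        k <- spec$downscale
        t <- t[rep(seq_len(TILE_PX), each = k), rep(seq_len(TILE_PX), each = k), ,
               drop = FALSE]
      }
      img[(r - 1) * s + seq_len(s), (cc - 1) * s + seq_len(s), ] <- t
    }
  }
  list(image = img, labels = layout, feature = spec$feature,
       tile_seeds = tile_seeds)
}
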