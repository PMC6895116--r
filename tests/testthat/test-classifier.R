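# Model head geometry, schedule mechanics, and CV steatosis pre-labeling.

test_that("output dimensionality per feature is fixed including ignore", {
  expected <- c(ballooning = 3L, inflammation = 4L, steatosis = 5L,
                fibrosis = 6L)
  for (f in names(expected)) {
    m <- build_model(f, seed = 1)
    expect_equal(m$n_out, expected[[f]])
    expect_equal(ncol(m$dense$W), expected[[f]])
  }
  expect_error(build_model("fibrosis", backbone = "resnet"), "unknown")
})

test_that("untrained softmax outputs are probability vectors, deterministic at inference", {
  m <- build_model("inflammation", seed = 2)
  tile <- generate_tile_image("inflammation", 1, seed = 3)
  q <- predict(m, list(tile$image, tile$image))
  expect_equal(rowSums(q), c(1, 1), tolerance = 1e-6)
  expect_equal(q[1, ], q[2, ], tolerance = 1e-12)
  # repeated inference calls are bit-identical
  expect_identical(predict(m, tile$image), predict(m, tile$image))
  expect_true(all(q > 0))
  expect_equal(colnames(q), c("0", "1", "2", "ignore"))
  expect_error(predict(m, array(0, dim = c(100, 100, 3))), "299")
})

test_that("the plateau rule multiplies lr by 0.2 after more than two stalled epochs", {
  sch <- training_schedule()   # fine-tuning defaults
  expect_equal(sch$initial_lr, 0.5e-4)
  expect_equal(sch$momentum, 0.9)
  expect_equal(sch$min_lr, 1e-7)
  # crafted loss trace: improvement, then three non-improving epochs
  losses <- c(1.0, 0.9, 0.95, 0.93, 0.94, 0.89, 0.91)
  lr <- plateau_lr_trace(losses, sch)
  # reduction takes effect on the epoch after the third stalled one
  expect_equal(lr[1:5], rep(0.5e-4, 5))
  expect_equal(lr[6], 0.5e-4 * 0.2)
  expect_equal(lr[7], 0.5e-4 * 0.2)
  # floor at min_lr under indefinite stalling
  lr2 <- plateau_lr_trace(c(1, rep(2, 40)), sch)
  expect_equal(min(lr2), 1e-7)
  expect_true(all(lr2 >= 1e-7))
})

test_that("oversampling equalises effective class frequencies", {
  labels <- rep(c("a", "b"), c(100, 25))
  idx <- withr::with_seed(4, oversample_indices(labels))
  expect_equal(as.vector(table(labels[idx])), c(100, 100))
  expect_setequal(unique(idx[labels[idx] == "b"]), which(labels == "b"))
})

test_that("augmentation is shape-preserving with exact flips", {
  img <- withr::with_seed(5, array(runif(299 * 299 * 3), c(299, 299, 3)))
  expect_identical(augment_tile(img), img)
  fh <- augment_tile(img, flip_h = TRUE)
  expect_equal(fh[, , 1], img[, 299:1, 1])
  fv <- augment_tile(img, flip_v = TRUE)
  expect_equal(fv[, , 2], img[299:1, , 2])
  # pure shift moves content; reflection keeps values from the source image
  sh <- augment_tile(img, dx = 10, dy = -5)
  expect_equal(dim(sh), dim(img))
  expect_true(all(sh %in% img))
  # rotation by 0 with no shift is the identity
  expect_identical(augment_tile(img, theta = 0), img)
})

test_that("training errors on degenerate label sets", {
  ts <- make_tile_set("ballooning", 2)
  m <- build_model("ballooning", seed = 6)
  expect_error(train(m, ts$tiles[1:2], c(0, 0)), ">= 2 classes")
  expect_error(train(m, ts$tiles, rep("7", 6)), "classes")
})

test_that("a short run on separable classes reduces the training loss", {
  spec <- feature_spec("steatosis")
  labs <- rep(c(0, 3), each = 12)
  tiles <- lapply(seq_along(labs), function(i) {
    generate_tile_image(spec, labs[i], seed = 100 + i)
  })
  sch <- training_schedule(initial_lr = 0.02, max_epochs = 4,
                           batch_size = 8L)
  m <- train(build_model(spec, seed = 7), tiles, labs, sch, seed = 8)
  expect_equal(nrow(m$history), 4)
  expect_lt(tail(m$history$train_loss, 1), m$history$train_loss[1])
  expect_true(m$trained)
  # checkpoints round-trip and predict identically
  dir <- withr::local_tempdir()
  save_checkpoint(m, file.path(dir, "m.ckpt"))
  m2 <- load_checkpoint(file.path(dir, "m.ckpt"))
  q1 <- predict(m, tiles[[1]])
  q2 <- predict(m2, tiles[[1]])
  expect_identical(q1, q2)
  meta <- jsonlite::fromJSON(readRDS(file.path(dir, "m.ckpt"))$meta)
  expect_equal(meta$feature, "steatosis")
  expect_equal(meta$scale, "high")
})

test_that("steatosis CV labeling segments bright round vacuoles", {
  dark <- array(0.15, dim = c(299, 299, 3))
  res <- steatosis_area_label(dark)
  expect_equal(res$area_fraction, 0)
  expect_equal(res$class, 0L)
  # the class intervals are half-open exactly as printed
  expect_equal(steatosis_area_label(dark, brightness_threshold = 0.5)$class, 0L)
  # area fraction recovered from generated tiles within 2 percentage points
  for (cls in 0:2) {
    for (s in 1:5) {
      t <- generate_tile_image("steatosis", cls, seed = 300 + 10 * cls + s)
      res <- steatosis_area_label(t$image)
      expect_lt(abs(res$area_fraction - t$generator_params$area_fraction),
                0.02)
    }
  }
  # a tile drawn at ~50% coverage classifies as 2
  mid <- generate_tile_image("steatosis", 2, seed = 12)
  expect_gt(mid$generator_params$area_fraction, 0.4)
  expect_equal(steatosis_area_label(mid$image)$class, 2L)
})

test_that("steatosis class boundaries are half-open at 5/33/66 percent", {
  expect_equal(steatosis_class_from_fraction(0.049), 0L)
  expect_equal(steatosis_class_from_fraction(0.05), 1L)
  expect_equal(steatosis_class_from_fraction(0.329), 1L)
  expect_equal(steatosis_class_from_fraction(0.33), 2L)
  expect_equal(steatosis_class_from_fraction(0.659), 2L)
  expect_equal(steatosis_class_from_fraction(0.66), 3L)
  expect_equal(steatosis_class_from_fraction(1), 3L)
})
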