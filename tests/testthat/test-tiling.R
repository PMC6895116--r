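# Two-scale non-overlapping tile grids and extraction.

test_that("grid tile counts follow floor(W/s) * floor(H/s) with borders dropped", {
  expect_equal(nrow(grid_tiles(598, 598, "high")), 4L)
  expect_equal(nrow(grid_tiles(897, 897, "low")), 1L)
  expect_equal(nrow(grid_tiles(300, 299, "high")), 1L)
  withr::with_seed(1, {
    for (i in 1:20) {
      w <- sample(299:2500, 1); h <- sample(299:2500, 1)
      g <- grid_tiles(w, h, "high")
      expect_equal(nrow(g), (w %/% 299L) * (h %/% 299L))
      # tiles disjoint and inside the image
      expect_true(all(g$x0 + 299 <= w), info = paste(w, h))
      expect_true(all(g$y0 + 299 <= h))
      expect_equal(anyDuplicated(g[, c("x0", "y0")]), 0L)
      expect_equal(g$x0, g$col * 299L)
      expect_equal(g$y0, g$row * 299L)
    }
  })
  expect_error(grid_tiles(200, 400, "high"), "smaller")
  expect_error(grid_tiles(896, 897, "low"), "smaller")
})

test_that("high-scale extraction is an identity crop", {
  img <- array(0.4, dim = c(598, 598, 3))
  img[300:598, 300:598, 2] <- 0.9
  g <- grid_tiles(598, 598, "high")
  t00 <- extract_tile(img, g[g$row == 0 & g$col == 0, ], "high")
  expect_equal(t00, array(0.4, dim = c(299, 299, 3)))
  t11 <- extract_tile(img, g[g$row == 1 & g$col == 1, ], "high")
  expect_true(all(t11[, , 2] == 0.9))
  expect_error(extract_tile(img, list(x0 = 598L, y0 = 0L), "high"), "bounds")
})

test_that("low-scale extraction block-averages 3x3 source pixels", {
  # constant region: averaging is invariant
  img <- array(0.25, dim = c(897, 897, 3))
  t <- extract_tile(img, list(x0 = 0L, y0 = 0L), "low")
  expect_equal(t, array(0.25, dim = c(299, 299, 3)))
  # random image: compare against an explicit per-block double loop
  img <- withr::with_seed(7, array(runif(897 * 897 * 3), dim = c(897, 897, 3)))
  t <- extract_tile(img, list(x0 = 0L, y0 = 0L), "low")
  blocks <- withr::with_seed(8, cbind(sample(1:299, 400, TRUE),
                                      sample(1:299, 400, TRUE)))
  for (i in seq_len(nrow(blocks))) {
    r <- blocks[i, 1]; cc <- blocks[i, 2]
    manual <- mean(img[(3 * r - 2):(3 * r), (3 * cc - 2):(3 * cc), 1])
    expect_equal(t[r, cc, 1], manual, tolerance = 1e-12)
  }
  # checkerboard of 3x3 blocks alternating 0/1 averages to the block value
  pat <- matrix(rep(c(0, 1), length.out = 299 * 299), 299, 299)
  big <- pat[rep(1:299, each = 3), rep(1:299, each = 3)]
  img2 <- array(rep(big, 3), dim = c(897, 897, 3))
  t2 <- extract_tile(img2, list(x0 = 0L, y0 = 0L), "low")
  expect_equal(t2[, , 1], pat, tolerance = 1e-12)
})

test_that("tiling a synthetic slide recovers each generated tile exactly", {
  layout <- matrix(c(0, 1, 3, "ignore"), 2, 2)
  w <- generate_wsi(layout, "steatosis", seed = 21)
  g <- grid_tiles(ncol(w$image), nrow(w$image), "high", slide_id = "s")
  expect_equal(nrow(g), 4L)
  for (i in seq_len(nrow(g))) {
    t <- extract_tile(w$image, g[i, ], "high")
    ref <- generate_tile_image("steatosis", layout[g$row[i] + 1, g$col[i] + 1],
                               seed = w$tile_seeds[g$row[i] + 1, g$col[i] + 1])
    expect_identical(t, ref$image)
  }
  # low scale: pixel replication then area mean is exact recovery
  wl <- generate_wsi(matrix(c(2, 4), 1, 2), "fibrosis", seed = 22)
  gl <- grid_tiles(ncol(wl$image), nrow(wl$image), "low")
  for (i in 1:2) {
    t <- extract_tile(wl$image, gl[i, ], "low")
    ref <- generate_tile_image("fibrosis", c(2, 4)[gl$col[i] + 1],
                               seed = wl$tile_seeds[1, gl$col[i] + 1])
    expect_equal(t, ref$image, tolerance = 1e-12)
  }
})

test_that("slides round-trip through PNG/TIFF and enforce the 0.44 um/px contract", {
  dir <- withr::local_tempdir()
  img <- withr::with_seed(3, array(runif(320 * 310 * 3), dim = c(310, 320, 3)))
  png::writePNG(img, file.path(dir, "s.png"))
  back <- read_slide(file.path(dir, "s.png"))
  expect_equal(dim(back), c(310, 320, 3))
  expect_equal(back, img, tolerance = 1 / 255)
  tiff::writeTIFF(img, file.path(dir, "s.tiff"))
  expect_equal(dim(read_slide(file.path(dir, "s.tiff"))), c(310, 320, 3))
  expect_error(read_slide(file.path(dir, "s.png"), um_per_px = 0.5),
               "0.44")
  expect_silent(read_slide(file.path(dir, "s.png"), um_per_px = 0.442))
})

test_that("write_tiles emits named PNGs plus a manifest", {
  dir <- withr::local_tempdir()
  img <- withr::with_seed(4, array(runif(598 * 598 * 3), dim = c(598, 598, 3)))
  manifest <- write_tiles(img, "high", dir, slide_id = "sl1")
  expect_equal(nrow(manifest), 4L)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  expect_true(file.exists(file.path(dir, "sl1_manifest.csv")))
  expect_equal(manifest$file[1], "sl1_high_0_0.png")
  back <- png::readPNG(file.path(dir, manifest$file[1]))
  expect_equal(back[, , 1:3], img[1:299, 1:299, ], tolerance = 1 / 255)
})
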