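# Synthetic tile, confidence and cohort generators.

test_that("feature taxonomies carry the fixed class counts and scales", {
  expect_equal(feature_spec("ballooning")$classes, 0:1)
  expect_equal(feature_spec("inflammation")$classes, 0:2)
  expect_equal(feature_spec("steatosis")$classes, 0:3)
  expect_equal(feature_spec("fibrosis")$classes, 0:4)
  for (f in feature_names()) {
    spec <- feature_spec(f)
    expect_equal(spec$n_classes, length(spec$classes) + 1L)
    expect_equal(spec$scale, if (f == "fibrosis") "low" else "high")
    expect_equal(spec$tile_px, 299L)
  }
  expect_equal(feature_spec("fibrosis")$source_px, 897L)
  expect_equal(feature_spec("fibrosis")$um_per_px, 1.32)
  expect_equal(feature_spec("steatosis")$um_per_px, 0.44)
})

test_that("steatosis tiles hit their class area-fraction intervals (pixel-counted)", {
  lo <- c(0, 0.05, 0.33, 0.66)
  hi <- c(0.05, 0.33, 0.66, 1)
  for (cls in 0:3) {
    fr <- vapply(1:200, function(s) {
      t <- generate_tile_image("steatosis", cls, seed = s)
      mask_frac <- mean(t$generator_params$vacuole_mask)
      # recorded fraction must equal the mask pixel count
      expect_equal(t$generator_params$area_fraction, mask_frac,
                   tolerance = 1e-12)
      mask_frac
    }, 0)
    expect_true(all(fr >= lo[cls + 1] & fr < hi[cls + 1]),
                info = sprintf("class %d: range %.4f..%.4f", cls,
                               min(fr), max(fr)))
  }
})

test_that("tile generation is deterministic and validates class labels", {
  a <- generate_tile_image("fibrosis", 3, seed = 11)
  b <- generate_tile_image("fibrosis", 3, seed = 11)
  expect_identical(a, b)
  c <- generate_tile_image("fibrosis", 3, seed = 12)
  expect_false(identical(a$image, c$image))
  expect_error(generate_tile_image("ballooning", 2, seed = 1),
               "invalid class")
  expect_error(generate_tile_image("steatosis", 4, seed = 1),
               "invalid class")
})

test_that("ballooning and inflammation generator records satisfy the class definitions", {
  t0 <- generate_tile_image("ballooning", 0, seed = 3)
  expect_equal(t0$generator_params$n_balloon_cells, 0L)
  for (s in 1:20) {
    t1 <- generate_tile_image("ballooning", 1, seed = s)
    expect_gte(t1$generator_params$n_balloon_cells, 1L)
    g0 <- generate_tile_image("inflammation", 0, seed = s)$generator_params
    expect_true(g0$cluster_cells < 3 && g0$disseminated < 5)
    g1 <- generate_tile_image("inflammation", 1, seed = s)$generator_params
    expect_true(g1$cluster_cells %in% 3:5 || g1$disseminated %in% 5:10)
    g2 <- generate_tile_image("inflammation", 2, seed = s)$generator_params
    expect_true(g2$cluster_cells > 5 || g2$disseminated > 10)
  }
})

test_that("tiles are 299x299 RGB rasters in [0, 1] for every class incl. ignore", {
  for (f in c("ballooning", "fibrosis")) {
    spec <- feature_spec(f)
    for (cl in class_labels(spec)) {
      img <- generate_tile_image(spec, cl, seed = 5)$image
      expect_equal(dim(img), c(299L, 299L, 3L))
      expect_true(all(img >= 0 & img <= 1))
    }
  }
})

test_that("confidence vectors are Dirichlet-centred on the true class", {
  q <- generate_tile_confidences(1, "ballooning", 50, seed = 1, n = 10000)
  expect_true(all(q >= 0))
  expect_lt(max(abs(rowSums(q) - 1)), 1e-9)
  # near one-hot in the high-concentration limit
  q1 <- generate_tile_confidences(2, "steatosis", 1e8, seed = 2, n = 50)
  expect_true(all(q1[, 3] > 0.999))
  # argmax recovers the true class for concentrated noise
  expect_gte(mean(max.col(q) == 2), 0.95)
  expect_error(generate_tile_confidences(1, "ballooning", 0), "concentration")
})

test_that("cohorts are deterministic with exact ground-truth mapping", {
  cuts <- c(0.5, 1.5, 2.5, 3.5)
  a <- generate_liver_cohort(20, "fibrosis", cuts, tiles_per_liver = 50,
                             seed = 9)
  b <- generate_liver_cohort(20, "fibrosis", cuts, tiles_per_liver = 50,
                             seed = 9)
  expect_identical(a, b)
  sc <- cohort_scores(a)
  expect_equal(sc$g, map_score(sc$true_x, cuts))
  # degenerate severity: all livers at state 0
  z <- generate_liver_cohort(10, "fibrosis", cuts, tiles_per_liver = 30,
                             severity_distribution = list(type = "fixed",
                                                          value = 0),
                             seed = 2)
  expect_true(all(vapply(z$livers, `[[`, 0, "g") == 0))
  # threshold count consistency
  expect_error(generate_liver_cohort(5, "ballooning", cuts), "inconsistent")
})

test_that("per-class liver counts match an independent re-simulation of the severity draws", {
  cuts <- c(0.5, 1.5, 2.5, 3.5)
  coh <- generate_liver_cohort(300, "fibrosis", cuts, tiles_per_liver = 20,
                               seed = 31)
  g <- vapply(coh$livers, `[[`, 0, "g")
  u_oracle <- withr::with_seed(31, stats::runif(300, 0, 4))
  g_oracle <- vapply(u_oracle, function(u) sum(u >= cuts), 0)
  expect_equal(as.vector(table(factor(g, levels = 0:4))),
               as.vector(table(factor(g_oracle, levels = 0:4))))
})

test_that("synthetic slides stitch tiles at the correct geometry", {
  w <- generate_wsi(matrix(c(0, 1, 2, 3), 2, 2), "steatosis", seed = 4)
  expect_equal(dim(w$image), c(598L, 598L, 3L))
  single <- generate_wsi(matrix(2), "steatosis", seed = 4)
  ref <- generate_tile_image("steatosis", 2, seed = 4 + 1000L + 1L)
  expect_identical(single$image, ref$image)
  # low-scale slides are pixel-replicated to the 897 px source footprint
  wl <- generate_wsi(matrix(0), "fibrosis", seed = 4)
  expect_equal(dim(wl$image), c(897L, 897L, 3L))
})

test_that("cohort CSV export round-trips liver table and confidences", {
  dir <- withr::local_tempdir()
  coh <- generate_liver_cohort(5, "ballooning", 0.5,
                               tiles_per_liver = 10, seed = 3)
  paths <- write_cohort_csv(coh, dir)
  livers <- read.csv(paths[1])
  expect_equal(nrow(livers), 5)
  conf <- read.csv(paths[2])
  expect_equal(nrow(conf), 50)
  expect_lt(max(abs(rowSums(conf[, grep("^q_", names(conf))]) - 1)), 1e-6)
})
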