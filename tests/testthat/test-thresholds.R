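# Discrete score mapping and Monte Carlo threshold fitting.

test_that("score mapping uses half-open intervals with an unbounded top", {
  t <- threshold_set(c(0.5, 1.5))
  expect_equal(map_score(0.1, t), 0L)
  expect_equal(map_score(0.5, t), 1L)    # x exactly at t_0 maps up
  expect_equal(map_score(1.5, t), 2L)
  expect_equal(map_score(99, t), 2L)
  expect_error(threshold_set(c(1, 0.5)), "increasing")
  expect_error(map_score(1, c(2, 1)), "increasing")
  # monotone non-decreasing in x
  xs <- sort(withr::with_seed(1, runif(500, 0, 4)))
  s <- map_score(xs, c(0.5, 1.5, 2.5, 3.5))
  expect_true(all(diff(s) >= 0))
  # sweep against an independent linear interval scan
  cuts <- c(0.31, 0.87, 2.2)
  xs <- withr::with_seed(2, runif(10000, 0, 3.5))
  oracle <- vapply(xs, function(x) {
    a <- 0L
    for (t in cuts) if (x >= t) a <- a + 1L else break
    a
  }, 0L)
  expect_equal(map_score(xs, cuts), oracle)
})

test_that("class weights are K over k_a, excluding absent classes with a warning", {
  expect_equal(unname(class_weights(rep(c(0, 1), c(50, 50)))), c(2, 2))
  expect_equal(unname(class_weights(rep(0, 7))), 1)
  expect_equal(unname(class_weights(rep(c(0, 1), c(90, 10)))), c(10 / 9, 10))
  expect_warning(w <- class_weights(c(0, 0, 2, 2), score_set = 0:2),
                 "absent")
  expect_equal(names(w), c("0", "2"))
})

test_that("mapping error implements the class-weighted quadratic sum", {
  # perfect mapping
  x <- c(0.2, 0.7, 1.9); g <- c(0, 1, 2)
  expect_equal(mapping_error(c(0.5, 1.5), x, g), 0)
  # one off-by-one error in a singleton class with f_a = 3
  x2 <- c(0.2, 1.2, 1.3); g2 <- c(0, 1, 1)
  expect_equal(mapping_error(0.1, x2, g2), 3)   # all mapped to 1
  expect_error(mapping_error(0.5, c(1, 2), c(0, 1, 1)), "mismatch")
  # random instances against an explicit double-loop oracle
  withr::with_seed(5, {
    for (i in 1:20) {
      n <- sample(10:80, 1)
      g <- sample(0:3, n, replace = TRUE)
      x <- runif(n, 0, 3)
      cuts <- sort(runif(3, 0, 3))
      expect_equal(mapping_error(cuts, x, g), brute_force_error(cuts, x, g),
                   tolerance = 1e-12)
    }
  })
  # invariant under record permutation
  withr::with_seed(6, {
    g <- sample(0:2, 50, replace = TRUE); x <- runif(50, 0, 2)
    p <- sample(50)
    expect_equal(mapping_error(c(0.6, 1.3), x, g),
                 mapping_error(c(0.6, 1.3), x[p], g[p]), tolerance = 1e-12)
  })
})

test_that("threshold initialization uses per-class 75th quantiles", {
  # constant class scores
  x <- c(rep(0.2, 4), rep(1.4, 3)); g <- rep(c(0, 1), c(4, 3))
  expect_equal(init_thresholds(x, g, 0:1)$cuts, 0.2)
  # linear interpolation between order statistics (type 7):
  # for n = 4 and p = 0.75, h = 3.25 -> x(3) + 0.25 (x(4) - x(3))
  x2 <- c(0.0, 0.1, 0.2, 0.3, rep(2, 3)); g2 <- rep(c(0, 1), c(4, 3))
  expect_equal(init_thresholds(x2, g2, 0:1)$cuts, 0.2 + 0.25 * 0.1)
  # disjoint class ranges put the cut strictly between the class means
  withr::with_seed(7, {
    x3 <- c(runif(30, 0, 0.8), runif(30, 1.2, 2)); g3 <- rep(0:1, each = 30)
    t3 <- init_thresholds(x3, g3, 0:1)$cuts
    expect_gt(t3, mean(x3[g3 == 0]))
    expect_lt(t3, mean(x3[g3 == 1]))
  })
  # empty class falls back to evenly spaced cuts, result still ordered
  x4 <- c(0.1, 0.2, 2.5, 2.6); g4 <- c(0, 0, 2, 2)
  t4 <- init_thresholds(x4, g4, 0:2)$cuts
  expect_equal(length(t4), 2)
  expect_true(all(diff(t4) > 0))
})

test_that("Monte Carlo fitting only accepts strict improvements and is reproducible", {
  coh <- generate_liver_cohort(80, "inflammation", c(0.6, 1.4),
                               tiles_per_liver = 120,
                               noise_concentration = 150, seed = 41)
  sc <- cohort_scores(coh)
  fit <- monte_carlo_fit(sc$x, sc$g, score_set = 0:2, seed = 42)
  expect_lte(fit$best_error, fit$error_trace[1])
  expect_true(all(diff(fit$error_trace) < 0))
  expect_equal(fit$best_error,
               mapping_error(fit$best_thresholds, sc$x, sc$g),
               tolerance = 1e-12)
  fit2 <- monte_carlo_fit(sc$x, sc$g, score_set = 0:2, seed = 42)
  expect_identical(fit[c("best_thresholds", "best_error", "iterations")],
                   fit2[c("best_thresholds", "best_error", "iterations")])
  expect_error(monte_carlo_fit(c(1, 2), c(1, 1)), "distinct")
  expect_warning(monte_carlo_fit(rep(1, 10), rep(c(0, 1), 5)), "identical")
})

test_that("the fit matches an exhaustive 0.01 grid on a small two-cut instance", {
  withr::with_seed(43, {
    sev <- list(type = "values",
                values = sample(seq(0, 2, by = 0.5), 40, replace = TRUE))
    coh <- generate_liver_cohort(40, "inflammation", c(0.6, 1.4),
                                 tiles_per_liver = 200,
                                 severity_distribution = sev,
                                 noise_concentration = 200, seed = 44)
  })
  sc <- cohort_scores(coh)
  fit <- monte_carlo_fit(sc$x, sc$g, score_set = 0:2, seed = 45)
  expect_equal(fit$best_error, grid_search_2cuts(sc$x, sc$g),
               tolerance = 1e-9)
})

test_that("fitted cuts recover the generating thresholds on a clean cohort", {
  true_cuts <- c(0.5, 1.5, 2.5, 3.5)
  coh <- generate_liver_cohort(150, "fibrosis", true_cuts,
                               tiles_per_liver = 300,
                               severity_distribution = list(type = "clustered",
                                                            sd = 0.2),
                               noise_concentration = 2000, seed = 51)
  sc <- cohort_scores(coh)
  fit <- monte_carlo_fit(sc$x, sc$g, score_set = 0:4, seed = 52)
  agree <- mean(map_score(sc$x, fit$best_thresholds) ==
                  map_score(sc$x, true_cuts))
  expect_gte(agree, 0.99)
  # each fitted cut close to a cut classifying identically (same data gap)
  expect_lt(max(abs(fit$best_thresholds$cuts - true_cuts)), 0.25)
})

test_that("train/test evaluation fits on the train split only", {
  true_cuts <- c(0.6, 1.4)
  mk <- function(seed) {
    coh <- generate_liver_cohort(100, "inflammation", true_cuts,
                                 tiles_per_liver = 200,
                                 severity_distribution = list(type = "clustered",
                                                              sd = 0.2),
                                 noise_concentration = 2000, seed = seed)
    cohort_scores(coh)
  }
  tr <- mk(61); te <- mk(62)
  res <- fit_and_evaluate(tr$x, tr$g, te$x, te$g,
                          train_ids = paste0("a", seq_len(nrow(tr))),
                          test_ids = paste0("b", seq_len(nrow(te))),
                          score_set = 0:2, seed = 63)
  # identically distributed splits at low noise: comparable agreement
  expect_lt(abs(res$train$cohen_kappa - res$test$cohen_kappa), 0.1)
  # bundle fields match standalone metric calls on the same predictions
  pred <- map_score(te$x, res$fit$best_thresholds)
  expect_equal(res$test$mae, mean_absolute_error(pred, te$g))
  expect_equal(res$test$cohen_kappa, cohen_kappa(pred, te$g))
  expect_error(fit_and_evaluate(tr$x, tr$g, te$x, te$g,
                                train_ids = c("s1", "s2"),
                                test_ids = c("s2", "s3")), "overlap")
})

test_that("threshold JSON round-trips", {
  dir <- withr::local_tempdir()
  fit <- list(best_thresholds = threshold_set(c(0.4, 1.1)), best_error = 2,
              seed = 1L, sigma = 0.15)
  class(fit) <- "mc_fit"
  p <- file.path(dir, "t.json")
  write_thresholds_json(fit, p, feature = "ballooning", fitted_on = 10)
  back <- read_thresholds_json(p)
  expect_equal(back$cuts, c(0.4, 1.1))
  expect_equal(back$feature, "ballooning")
})
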