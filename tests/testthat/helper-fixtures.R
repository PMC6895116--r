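# Shared fixtures: random confidence matrices and brute-force oracles.

# Random confidence rows over C classes (ignore last), rows sum to 1.
random_confidences <- function(n, C, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(stats::rexp(n * C), n, C)
    g / rowSums(g)
  })
}

# Brute-force weighted-error evaluation (independent of mapping_error):
# explicit double loop over classes and records.
brute_force_error <- function(cuts, x, g) {
  K <- length(g)
  E <- 0
  for (a in sort(unique(g))) {
    k_a <- sum(g == a)
    f_a <- K / k_a
    for (k in which(g == a)) {
      s_k <- sum(x[k] >= cuts)   # interval index by linear scan
      E <- E + f_a * (s_k - g[k])^2
    }
  }
  E
}

# Exhaustive 0.01-resolution grid search for two interior cuts.
grid_search_2cuts <- function(x, g, score_set = 0:2, step = 0.01) {
  w_tab <- suppressWarnings(class_weights(g, score_set))
  f <- w_tab[as.character(g)]
  ts <- seq(0, max(score_set), by = step)
  best <- Inf
  for (t0 in ts) {
    s0 <- (x >= t0)
    for (t1 in ts[ts > t0]) {
      s <- s0 + (x >= t1)
      e <- sum(f * (s - g)^2)
      if (e < best) best <- e
    }
  }
  best
}

# Quick labeled synthetic tile set for one feature.
make_tile_set <- function(feature, n_per_class, seed_base = 0) {
  spec <- feature_spec(feature)
  labs <- rep(class_labels(spec), each = n_per_class)
  tiles <- lapply(seq_along(labs), function(i) {
    generate_tile_image(spec, labs[i], seed = seed_base + i)
  })
  list(tiles = tiles, labels = labs, spec = spec)
}
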