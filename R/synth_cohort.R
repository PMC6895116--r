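# Synthetic confidence vectors and liver cohorts with known ground truth.
#
# The cohort generator emulates the stair-like structure of continuous
# score vs pathologist score: each liver gets a latent severity u in
# [0, max class]; its tiles are drawn from the two-point class mixture on
# floor(u)/ceil(u) with weights (1 - frac(u), frac(u)), so the noise-free
# per-liver weighted-class mean equals u exactly, and the discrete ground
# truth is u mapped through a known threshold set.

#' Simulate a softmax confidence vector for a tile of known class
#'
#' Draws from a Dirichlet distribution centred on the one-hot vector of
#' the true class: the true class gets concentration `noise_concentration`
#' and every other class (including ignore) concentration 1. Large
#' concentrations approach the one-hot limit; small ones emulate a
#' confused classifier.
#'
#' @param true_class Integer class label or `"ignore"`.
#' @param feature A [feature_spec()] or feature name.
#' @param noise_concentration Positive real; Dirichlet weight of the true
#'   class.
#' @param seed Integer seed.
#' @param n Number of vectors to draw.
#' @return Numeric matrix `n` x `n_classes` (ignore last); each row sums
#'   to 1.
#' @examples
#' q <- generate_tile_confidences(1, "ballooning", 50, seed = 1)
#' rowSums(q)  # 1
#' @export
generate_tile_confidences <- function(true_class, feature,
                                      noise_concentration, seed = 1L,
                                      n = 1L) {
  spec <- if (inherits(feature, "feature_spec")) feature else feature_spec(feature)
  stopifnot(noise_concentration > 0)
  idx <- resolve_class(spec, true_class)
  C <- spec$n_classes
  alpha <- rep(1, C)
  alpha[idx + 1L] <- noise_concentration
  local_seed(seed, {
    g <- matrix(stats::rgamma(n * C, shape = rep(alpha, each = n)), nrow = n)
    g / rowSums(g)
  })
}

# Dirichlet rows for a vector of 0-based class indices (vectorised).
rdirichlet_rows <- function(class_idx, C, concentration) {
  n <- length(class_idx)
  alpha <- matrix(1, n, C)
  alpha[cbind(seq_len(n), class_idx + 1L)] <- concentration
  g <- matrix(stats::rgamma(n * C, shape = alpha), n, C)
  g / rowSums(g)
}

#' Simulate a cohort of livers with known continuous and discrete scores
#'
#' Each liver receives a latent severity \eqn{u \in [0, m]} (m = maximal
#' class), converted to a two-point tile-class mixture on
#' \eqn{\lfloor u \rfloor, \lceil u \rceil} whose mean is exactly u.
#' A fraction of tiles is replaced by ignore-class tiles. Per-tile softmax
#' confidences are drawn Dirichlet-centred on the true tile class, and the
#' discrete ground truth is `map_score(u, true_thresholds)`.
#'
#' @param n_livers Number of livers (>= 1).
#' @param feature A [feature_spec()] or feature name.
#' @param true_thresholds A [threshold_set()] (or numeric cut vector) used
#'   to derive the discrete ground truth.
#' @param tiles_per_liver Tiles simulated per liver (default 500).
#' @param severity_distribution `list(type = "uniform")` (default);
#'   `list(type = "fixed", value = u)`;
#'   `list(type = "values", values = u_vec)`; or
#'   `list(type = "clustered", sd = 0.25)` — severities normal around a
#'   uniformly drawn integer disease state, clamped to \[0, m\], giving
#'   the stair-like continuous-vs-discrete structure of real cohorts.
#' @param noise_concentration Dirichlet concentration of the true class.
#' @param ignore_rate Fraction of ignore-class tiles.
#' @param mixture_sampling `"exact"` (default): the realized tile-class
#'   composition matches the two-point mixture weights exactly (up to
#'   integer rounding), so the only score noise is the confidence noise;
#'   `"binomial"`: each tile's class is drawn independently, adding
#'   binomial composition noise.
#' @param seed Integer seed; same seed gives a bit-identical cohort.
#' @return A `synthetic_cohort` list: `livers` (list of records with
#'   `sample_id`, `confidences` matrix, `true_classes`, `true_x`, `g`),
#'   `feature`, `true_thresholds`, `noise_spec`, `seed`.
#' @export
generate_liver_cohort <- function(n_livers, feature, true_thresholds,
                                  tiles_per_liver = 500L,
                                  severity_distribution = list(type = "uniform"),
                                  noise_concentration = 100,
                                  ignore_rate = 0.05,
                                  mixture_sampling = c("exact", "binomial"),
                                  seed = 1L) {
  mixture_sampling <- match.arg(mixture_sampling)
  spec <- if (inherits(feature, "feature_spec")) feature else feature_spec(feature)
  stopifnot(n_livers >= 1, tiles_per_liver >= 1, noise_concentration > 0)
  cuts <- threshold_cuts(true_thresholds)
  if (length(cuts) != length(spec$classes) - 1L) {
    stop(sprintf("threshold count %d inconsistent with %d classes of '%s'",
                 length(cuts), length(spec$classes), spec$feature),
         call. = FALSE)
  }
  m <- max(spec$classes)
  C <- spec$n_classes
  local_seed(seed, {
    u <- switch(severity_distribution$type,
      uniform = stats::runif(n_livers, 0, m),
      fixed   = rep(severity_distribution$value, n_livers),
      values  = rep_len(severity_distribution$values, n_livers),
      clustered = pmin(pmax(sample(0:m, n_livers, replace = TRUE) +
                              stats::rnorm(n_livers,
                                           0, severity_distribution$sd %||% 0.25),
                            0), m),
      stop("unknown severity_distribution type", call. = FALSE))
    stopifnot(all(u >= 0), all(u <= m))
    livers <- vector("list", n_livers)
    for (k in seq_len(n_livers)) {
      lo <- floor(u[k]); fr <- u[k] - lo
      n_ign <- round(tiles_per_liver * ignore_rate)
      n_eff <- tiles_per_liver - n_ign
      if (mixture_sampling == "exact") {
        n_hi <- round(n_eff * fr)
        cls <- rep(c(lo + 1L, lo), c(n_hi, n_eff - n_hi))
      } else {
        cls <- lo + stats::rbinom(n_eff, 1L, fr)
      }
      cls <- sample(c(cls, rep(spec$ignore_index, n_ign)))
      q <- rdirichlet_rows(cls, C, noise_concentration)
      livers[[k]] <- list(sample_id = sprintf("L%04d", k),
                          confidences = q, true_classes = cls,
                          true_x = u[k],
                          g = map_score(u[k], cuts))
    }
    structure(list(livers = livers, feature = spec$feature,
                   true_thresholds = cuts,
                   noise_spec = list(concentration = noise_concentration,
                                     ignore_rate = ignore_rate),
                   seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d livers, feature %s, cuts {%s}\n",
              length(x$livers), x$feature,
              paste(signif(x$true_thresholds, 4), collapse = ", ")))
  invisible(x)
}

#' Continuous and discrete scores of a synthetic cohort
#'
#' Runs every liver of the cohort through the aggregation chain
#' (ignore filtering, renormalization, weighted class, per-liver mean).
#'
#' @param cohort A [generate_liver_cohort()] result.
#' @return Data frame: `sample_id`, `x` (aggregated continuous score),
#'   `true_x`, `g` (discrete ground truth), `n_tiles`, `n_retained`.
#' @export
cohort_scores <- function(cohort) {
  rows <- lapply(cohort$livers, function(lv) {
    ls <- aggregate_liver(lv$confidences, sample_id = lv$sample_id,
                          feature = cohort$feature)
    data.frame(sample_id = lv$sample_id, x = ls$x, true_x = lv$true_x,
               g = lv$g, n_tiles = ls$n_tiles_total,
               n_retained = ls$n_tiles_retained,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a synthetic cohort to CSV files
#'
#' @param cohort A [generate_liver_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths of the liver table and the per-tile
#'   confidence table.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- feature_spec(cohort$feature)
  livers <- data.frame(
    sample_id = vapply(cohort$livers, `[[`, "", "sample_id"),
    g = vapply(cohort$livers, `[[`, 0, "g"),
    true_x = vapply(cohort$livers, `[[`, 0, "true_x"))
  fl <- file.path(dir, sprintf("cohort_%s_livers.csv", cohort$feature))
  utils::write.csv(livers, fl, row.names = FALSE)
  conf <- do.call(rbind, lapply(cohort$livers, function(lv) {
    cbind(data.frame(sample_id = lv$sample_id,
                     tile = seq_len(nrow(lv$confidences))),
          as.data.frame(lv$confidences))
  }))
  names(conf)[-(1:2)] <- paste0("q_", class_labels(spec))
  fc <- file.path(dir, sprintf("cohort_%s_confidences.csv", cohort$feature))
  utils::write.csv(conf, fc, row.names = FALSE)
  invisible(c(fl, fc))
}
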