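# Mapping continuous liver scores to discrete pathologist-like scores.
#
# An ordered threshold set t_0 < t_1 < ... divides the score axis into
# half-open intervals: s(x) = 0 for 0 <= x < t_0, 1 for t_0 <= x < t_1,
# ..., and the maximal score for x >= t_last. Thresholds are fitted by a
# Monte Carlo search minimising the class-weighted quadratic error
#   E = sum_{a in A} f_a sum_{g_k = a} (s_k(x) - g_k)^2,  f_a = K / k_a,
# starting from the per-class 75th quantiles and perturbing the incumbent
# best set with N(0, sigma^2) noise (sigma = 0.15), accepting strict
# improvements only, until the error converges.

#' Construct an ordered threshold set
#'
#' @param cuts Strictly increasing numeric cut points (|A| - 1 interior
#'   cuts for score set A).
#' @param feature Optional feature name carried along.
#' @return A `threshold_set`.
#' @export
threshold_set <- function(cuts, feature = NULL) {
  cuts <- as.numeric(cuts)
  if (is.unsorted(cuts, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  structure(list(cuts = cuts, feature = feature), class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set>%s cuts: %s\n",
              if (is.null(x$feature)) "" else paste0(" ", x$feature),
              paste(signif(x$cuts, 5), collapse = " < ")))
  invisible(x)
}

threshold_cuts <- function(t) {
  cuts <- if (inherits(t, "threshold_set")) t$cuts else as.numeric(t)
  if (is.unsorted(cuts, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  cuts
}

#' Map continuous scores to discrete scores
#'
#' Half-open intervals: score a is assigned when
#' \eqn{t_{a-1} \le x < t_a}; x exactly at a cut maps to the interval
#' above it; x at or above the last cut maps to the maximal score.
#'
#' @param x Numeric vector of continuous scores (>= 0).
#' @param thresholds A [threshold_set()] or numeric cut vector.
#' @return Integer vector of discrete scores in 0 ... length(cuts).
#' @examples
#' map_score(c(0.1, 0.5, 1.49, 2.7), c(0.5, 1.5))  # 0 1 1 2
#' @export
map_score <- function(x, thresholds) {
  cuts <- threshold_cuts(thresholds)
  stopifnot(all(x >= 0))
  findInterval(x, cuts, left.open = FALSE)
}

#' Class-imbalance weights f_a = K / k_a
#'
#' @param g Integer vector of ground-truth scores.
#' @param score_set The full score set A (defaults to the observed
#'   values); members of A absent from `g` are excluded with a warning.
#' @return Named numeric vector of weights for the present classes.
#' @examples
#' class_weights(rep(c(0, 1), c(90, 10)))  # 10/9, 10
#' @export
class_weights <- function(g, score_set = sort(unique(g))) {
  K <- length(g)
  k_a <- vapply(score_set, function(a) sum(g == a), 0)
  names(k_a) <- score_set
  absent <- score_set[k_a == 0]
  if (length(absent)) {
    warning(sprintf("score value(s) %s absent from ground truth; excluded from the error",
                    paste(absent, collapse = ", ")), call. = FALSE)
  }
  K / k_a[k_a > 0]
}

#' Class-weighted quadratic mapping error
#'
#' \eqn{E = \sum_{a \in A} f_a \sum_{g_k = a} (s_k(x) - g_k)^2} with
#' \eqn{f_a = K / k_a}.
#'
#' @param thresholds A [threshold_set()] or cut vector.
#' @param x Continuous scores, aligned with `g`.
#' @param g Ground-truth discrete scores.
#' @param weights Optional precomputed [class_weights()] (recomputed from
#'   `g` otherwise).
#' @return The scalar error E.
#' @export
mapping_error <- function(thresholds, x, g, weights = NULL) {
  if (length(x) != length(g)) stop("x and g length mismatch", call. = FALSE)
  s <- map_score(x, thresholds)
  if (is.null(weights)) weights <- suppressWarnings(class_weights(g))
  f <- weights[as.character(g)]
  f[is.na(f)] <- 0   # classes excluded from the weight table
  sum(f * (s - g)^2)
}

#' Initialize thresholds at per-class 75th quantiles
#'
#' For every non-maximal score a present in the ground truth, t_a is the
#' 75th percentile (linear interpolation between order statistics,
#' `stats::quantile` type 7) of the continuous scores with ground truth
#' a; empty classes fall back to evenly spaced cuts over the x range.
#' The result is sorted and exact collisions are separated by 1e-6.
#'
#' @param x Continuous scores.
#' @param g Ground-truth discrete scores.
#' @param score_set The full score set A (defaults to 0 ... max(g)).
#' @return A [threshold_set()].
#' @export
init_thresholds <- function(x, g, score_set = 0:max(g)) {
  lower <- score_set[-length(score_set)]
  t0 <- vapply(lower, function(a) {
    xa <- x[g == a]
    if (length(xa) == 0) NA_real_ else
      unname(stats::quantile(xa, 0.75, type = 7))
  }, 0)
  if (anyNA(t0)) {
    even <- seq(min(x), max(x), length.out = length(lower) + 2L)[-1]
    even <- even[seq_along(lower)]
    t0[is.na(t0)] <- even[is.na(t0)]
  }
  threshold_set(repair_cuts(t0))
}

# Sort ascending and separate exact collisions by 1e-6.
repair_cuts <- function(cuts) {
  cuts <- sort(cuts)
  for (i in seq_along(cuts)[-1]) {
    if (cuts[i] <= cuts[i - 1]) cuts[i] <- cuts[i - 1] + 1e-6
  }
  cuts
}

#' Fit thresholds by Monte Carlo search
#'
#' Starting from the quantile initialization, each iteration perturbs the
#' incumbent best cuts with independent N(0, sigma^2) noise, repairs the
#' ordering (sort; exact collisions separated by 1e-6), evaluates E, and
#' accepts the proposal only if strictly lower. The search stops after
#' `stop_after` consecutive proposals without improvement or `max_iter`
#' proposals in total.
#'
#' @param x Continuous scores of the fit set.
#' @param g Ground-truth discrete scores.
#' @param score_set Full score set A (default 0 ... max(g)).
#' @param sigma Proposal standard deviation (default 0.15).
#' @param seed Integer seed; the fit is fully reproducible.
#' @param stop_after Consecutive non-improving proposals tolerated.
#' @param max_iter Hard proposal cap.
#' @return An `mc_fit` list: `best_thresholds` ([threshold_set()]),
#'   `best_error`, `error_trace` (strictly decreasing, one entry per
#'   accepted improvement, starting at the initialization), `iterations`,
#'   `sigma`, `seed`.
#' @export
monte_carlo_fit <- function(x, g, score_set = 0:max(g), sigma = 0.15,
                            seed = 1L, stop_after = 2000L,
                            max_iter = 100000L) {
  if (length(x) != length(g)) stop("x and g length mismatch", call. = FALSE)
  if (length(unique(g)) < 2L) {
    stop("need >= 2 distinct ground-truth classes", call. = FALSE)
  }
  weights <- suppressWarnings(class_weights(g, score_set))
  init <- init_thresholds(x, g, score_set)
  best <- init$cuts
  best_e <- mapping_error(best, x, g, weights)
  trace <- best_e
  degenerate <- length(unique(x)) == 1L
  if (degenerate) {
    warning("all continuous scores identical; returning initialization",
            call. = FALSE)
  }
  it <- 0L
  local_seed(seed, {
    if (!degenerate) {
      stall <- 0L
      while (stall < stop_after && it < max_iter) {
        it <- it + 1L
        prop <- repair_cuts(best + stats::rnorm(length(best), 0, sigma))
        e <- mapping_error(prop, x, g, weights)
        if (e < best_e) {
          best <- prop; best_e <- e
          trace <- c(trace, e)
          stall <- 0L
        } else stall <- stall + 1L
      }
    }
  })
  structure(list(best_thresholds = threshold_set(best),
                 best_error = best_e, error_trace = trace,
                 iterations = it, sigma = sigma, seed = seed,
                 initialization = init),
            class = "mc_fit")
}

#' @export
print.mc_fit <- function(x, ...) {
  cat(sprintf("<mc_fit> E = %.6g after %d proposals (%d improvements), cuts: %s\n",
              x$best_error, x$iterations, length(x$error_trace) - 1L,
              paste(signif(x$best_thresholds$cuts, 5), collapse = " < ")))
  invisible(x)
}

#' Fit thresholds on a train split and evaluate on a held-back test split
#'
#' Thresholds are determined on the training livers only; the full metric
#' bundle (MAE, Cohen's kappa, weighted precision/recall/F1, accuracy,
#' confusion matrix) is reported for both splits.
#'
#' @param train_x,train_g Continuous scores and ground truth of the fit
#'   set.
#' @param test_x,test_g Held-back test set.
#' @param train_ids,test_ids Optional sample ids; overlap is an error.
#' @param score_set Full score set A.
#' @param ... Passed to [monte_carlo_fit()].
#' @return List: `fit` (the `mc_fit`), `train` and `test` metric bundles
#'   (see [metric_bundle()]), and the mapped test scores.
#' @export
fit_and_evaluate <- function(train_x, train_g, test_x, test_g,
                             train_ids = NULL, test_ids = NULL,
                             score_set = 0:max(c(train_g, test_g)), ...) {
  if (!is.null(train_ids) && !is.null(test_ids) &&
      length(intersect(train_ids, test_ids)) > 0L) {
    stop("train and test sample ids overlap", call. = FALSE)
  }
  fit <- monte_carlo_fit(train_x, train_g, score_set = score_set, ...)
  cuts <- fit$best_thresholds
  pred_train <- map_score(train_x, cuts)
  pred_test <- map_score(test_x, cuts)
  list(fit = fit,
       train = metric_bundle(pred_train, train_g, labels = score_set),
       test = metric_bundle(pred_test, test_g, labels = score_set),
       predicted_test = pred_test)
}

#' Serialize fitted thresholds to JSON
#'
#' @param fit An `mc_fit` (or [threshold_set()]).
#' @param path Output path.
#' @param feature Feature name recorded in the file.
#' @param fitted_on Number of livers the fit used.
#' @return The path, invisibly.
#' @export
write_thresholds_json <- function(fit, path, feature = NULL,
                                  fitted_on = NA_integer_) {
  if (inherits(fit, "mc_fit")) {
    obj <- list(feature = feature %||% fit$best_thresholds$feature,
                cuts = fit$best_thresholds$cuts, error = fit$best_error,
                fitted_on = fitted_on, seed = fit$seed, sigma = fit$sigma)
  } else {
    obj <- list(feature = feature, cuts = threshold_cuts(fit),
                fitted_on = fitted_on)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_set(obj$cuts, feature = obj$feature)
}
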