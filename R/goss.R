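#' GOSS boosting configuration
#'
#' Defaults follow the conventional one-side-sampling rates (keep the top 20%
#' of samples by absolute gradient, randomly add 10% of the rest) with 50
#' shallow trees; the sampled small-gradient rows are up-weighted by
#' `(1 - o) / p` inside the split gain so the gradient distribution is
#' unbiased.
#'
#' @param o large-gradient sampling rate in (0, 1].
#' @param p small-gradient sampling rate in [0, 1); `o + p <= 1`.
#' @param n_trees number of boosting rounds (>= 0).
#' @param max_depth maximum tree depth (>= 1).
#' @param learning_rate shrinkage applied to each tree's contribution.
#' @param min_samples_split minimum sampled rows required to attempt a split.
#' @param seed optional integer seed.
#' @return a `goss_config` list.
#' @export
goss_config <- function(o = 0.2, p = 0.1, n_trees = 50, max_depth = 3,
                        learning_rate = 0.1, min_samples_split = 2,
                        seed = NULL) {
  if (o <= 0 || o > 1) stop("goss_config: o must lie in (0, 1]")
  if (p < 0 || p >= 1) stop("goss_config: p must lie in [0, 1)")
  if (o + p > 1) stop("goss_config: o + p must be <= 1")
  if (n_trees < 0) stop("goss_config: n_trees must be >= 0")
  if (max_depth < 1) stop("goss_config: max_depth must be >= 1")
  if (learning_rate <= 0) stop("goss_config: learning_rate must be > 0")
  if (min_samples_split < 2) stop("goss_config: min_samples_split must be >= 2")
  structure(list(o = o, p = p, n_trees = n_trees, max_depth = max_depth,
                 learning_rate = learning_rate,
                 min_samples_split = min_samples_split, seed = seed),
            class = "goss_config")
}

#' Gradient-based one-side sampling
#'
#' Sorts samples by decreasing absolute gradient (ties by index), keeps the
#' top `floor(o * n)` as the large-gradient set OD, and draws `floor(p * n)`
#' of the remainder uniformly without replacement as the small-gradient set
#' PD. PD members carry weight `(1 - o) / p` in the split gain; OD members
#' carry weight 1.
#'
#' @param gradients numeric vector of per-sample gradients (length >= 2).
#' @param o,p sampling rates, see [goss_config()].
#' @return list with `large_idx`, `small_idx`, `idx` (their union, OD first)
#'   and `weights` aligned with `idx`.
#' @export
goss_sample <- function(gradients, o, p) {
  n <- length(gradients)
  if (n < 2L) stop("goss_sample: need at least 2 samples")
  n_large <- floor(o * n)
  if (n_large < 1L) stop("goss_sample: floor(o * n) must be >= 1")
  n_small <- floor(p * n)
  ord <- order(-abs(gradients))            # stable: ties keep index order
  large_idx <- ord[seq_len(n_large)]
  rest <- ord[-seq_len(n_large)]
  small_idx <- if (n_small > 0L) sort(sample(rest, n_small)) else integer(0)
  w_small <- if (p > 0) (1 - o) / p else numeric(0)
  list(large_idx = large_idx, small_idx = small_idx,
       idx = c(large_idx, small_idx),
       weights = c(rep(1, n_large), rep(w_small, n_small)))
}

#' Weighted split information gain
#'
#' The one-side-sampling gain of splitting a feature at threshold `d`:
#' `(1/n) * ((sum_left w h)^2 / n_left + (sum_right w h)^2 / n_right)` where
#' `n` is the sampled count, sides are `values <= d` versus `values > d`,
#' the weighted gradient sums use weight 1 for large-gradient rows and
#' `(1 - o) / p` for small-gradient rows, and `n_left`/`n_right` are
#' unweighted side counts. Returns `NA` if either side is empty.
#'
#' @param values sampled feature column.
#' @param gradients sampled gradients, same length.
#' @param weights sampled weights, same length.
#' @param d split threshold.
#' @return non-negative scalar gain, or `NA_real_` for an invalid split.
#' @export
split_gain <- function(values, gradients, weights, d) {
  n <- length(values)
  stopifnot(length(gradients) == n, length(weights) == n)
  left <- values <= d
  n_left <- sum(left)
  n_right <- n - n_left
  if (n_left == 0L || n_right == 0L) return(NA_real_)
  wh <- weights * gradients
  s_left <- sum(wh[left])
  s_right <- sum(wh) - s_left
  (s_left^2 / n_left + s_right^2 / n_right) / n
}

# Best split for one feature at one node, vectorized over the candidate
# thresholds (midpoints of consecutive sorted unique sampled values).
# Returns NULL when no valid threshold exists.
best_split_feature <- function(v, wh, n) {
  ord <- order(v)
  vs <- v[ord]
  cw <- cumsum(wh[ord])
  total <- cw[n]
  cut <- which(vs[-n] < vs[-1])            # last index of each left block
  if (length(cut) == 0L) return(NULL)
  n_left <- cut
  s_left <- cw[cut]
  gain <- (s_left^2 / n_left + (total - s_left)^2 / (n - n_left)) / n
  best <- which.max(gain)
  list(threshold = (vs[cut[best]] + vs[cut[best] + 1L]) / 2,
       gain = gain[best])
}

# Recursive greedy tree growth on the sampled rows of a node. `idx` indexes
# into the sampled arrays. A node splits only when the best gain strictly
# exceeds the parent's own score (1/n)(sum wh)^2 / n — equal gain means the
# split separates nothing, e.g. all-zero gradients.
grow_node <- function(x, wh, w, idx, depth, config, importance_env) {
  n <- length(idx)
  leaf <- function() {
    sw <- sum(w[idx])
    list(leaf = TRUE, value = if (sw > 0) sum(wh[idx]) / sw else 0)
  }
  if (depth >= config$max_depth || n < config$min_samples_split) return(leaf())
  parent_score <- sum(wh[idx])^2 / n / n
  best <- NULL
  for (j in seq_len(ncol(x))) {
    cand <- best_split_feature(x[idx, j], wh[idx], n)
    if (!is.null(cand) && (is.null(best) || cand$gain > best$gain)) {
      best <- c(cand, feature = j)
    }
  }
  if (is.null(best) || best$gain <= parent_score + 1e-12) return(leaf())
  imp <- importance_env$imp
  imp[best$feature] <- imp[best$feature] + best$gain
  importance_env$imp <- imp
  go_left <- x[idx, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_node(x, wh, w, idx[go_left], depth + 1L, config,
                        importance_env),
       right = grow_node(x, wh, w, idx[!go_left], depth + 1L, config,
                         importance_env))
}

tree_predict <- function(node, x) {
  out <- numeric(nrow(x))
  recurse <- function(node, rows) {
    if (length(rows) == 0L) return()
    if (node$leaf) {
      out[rows] <<- node$value
      return()
    }
    go_left <- x[rows, node$feature] <= node$threshold
    recurse(node$left, rows[go_left])
    recurse(node$right, rows[!go_left])
  }
  recurse(node, seq_len(nrow(x)))
  out
}

#' Fit a GOSS gradient-boosted tree ensemble and feature importances
#'
#' Boosting with squared loss: the working response each round is the
#' residual (the negative gradient), one-side sampled via [goss_sample()];
#' each tree greedily picks, per node, the feature/threshold pair maximizing
#' the weighted gain of [split_gain()] over midpoint candidate thresholds.
#' A feature's importance is the sum of the chosen gains over all split
#' nodes of all trees; features never chosen score exactly 0.
#'
#' @param x numeric matrix or data.frame of features.
#' @param y numeric target vector.
#' @param config a [goss_config()].
#' @return a `goss_model` list with `trees`, `f0`, `learning_rate`,
#'   `feature_names` and `importance` (named non-negative vector in input
#'   column order).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- 2 * x[, 2] + rnorm(200, sd = 0.1)
#' fit <- fit_goss_gbdt(x, y, goss_config(n_trees = 20, seed = 1))
#' names(which.max(fit$importance))   # "b"
#' @export
fit_goss_gbdt <- function(x, y, config = goss_config()) {
  stopifnot(inherits(config, "goss_config"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (ncol(x) < 2L) stop("fit_goss_gbdt: need at least 2 features")
  n <- nrow(x)
  if (length(y) != n) stop("fit_goss_gbdt: x and y sizes differ")
  if (n < config$min_samples_split) stop("fit_goss_gbdt: too few rows")
  if (!is.null(config$seed)) set.seed(config$seed)

  f0 <- mean(y)
  pred <- rep(f0, n)
  trees <- vector("list", config$n_trees)
  imp_env <- new.env(parent = emptyenv())
  imp_env$imp <- stats::setNames(numeric(ncol(x)), colnames(x))

  n_used <- 0L
  for (t in seq_len(config$n_trees)) {
    h <- y - pred                               # negative gradient of 0.5*sse
    smp <- goss_sample(h, config$o, config$p)
    xs <- x[smp$idx, , drop = FALSE]
    wh <- smp$weights * h[smp$idx]
    root <- grow_node(xs, wh, smp$weights, seq_along(smp$idx), 0L, config,
                      imp_env)
    if (root$leaf && root$value == 0) break     # nothing left to fit
    trees[[t]] <- root
    pred <- pred + config$learning_rate * tree_predict(root, x)
    n_used <- t
  }
  structure(list(trees = trees[seq_len(n_used)], f0 = f0,
                 learning_rate = config$learning_rate,
                 feature_names = colnames(x), importance = imp_env$imp),
            class = "goss_model")
}

#' @export
predict.goss_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  pred <- rep(object$f0, nrow(x))
  for (tree in object$trees) {
    pred <- pred + object$learning_rate * tree_predict(tree, x)
  }
  pred
}

#' Top-k feature selection by importance weight
#'
#' @param importance named non-negative numeric vector (e.g. the
#'   `importance` field of a [fit_goss_gbdt()] model).
#' @param k number of features to keep, `1 <= k <= length(importance)`.
#' @return character vector of k feature names, by decreasing weight; ties
#'   broken by input column order.
#' @examples
#' w <- c(co2 = 29.74, light = 13.20, temp = 13.09, pm25 = 6.54, h2s = 5.08)
#' select_features(w, 4)
#' @export
select_features <- function(importance, k) {
  if (is.null(names(importance)) || anyNA(importance)) {
    stop("select_features: importance must be a named numeric vector")
  }
  if (k < 1 || k > length(importance)) stop("select_features: k out of range")
  ord <- order(-importance)                # stable sort: ties keep input order
  names(importance)[ord][seq_len(k)]
}

#' Write a feature-importance report as a two-column CSV
#'
#' Columns `parameter`, `weight`, sorted by decreasing weight.
#'
#' @param importance named numeric vector.
#' @param path output file path.
#' @export
write_importance_csv <- function(importance, path) {
  ord <- order(-importance)
  utils::write.csv(data.frame(parameter = names(importance)[ord],
                              weight = unname(importance)[ord]),
                   path, row.names = FALSE)
  invisible(path)
}
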