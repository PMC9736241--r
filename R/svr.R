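#' SVR hyperparameter triple
#'
#' Penalty `C`, radial-basis width `g` and insensitive-loss half-width `eps`.
#' `g` enters the kernel as `exp(-||mi - mj||^2 / g^2)`, i.e. the solver's
#' RBF coefficient is `1 / g^2` (see [kernel_coefficient()]).
#'
#' @param C penalty coefficient, > 0.
#' @param g kernel width, > 0.
#' @param eps insensitive-loss half-width, >= 0.
#' @return an `svr_params` object.
#' @export
svr_params <- function(C, g, eps) {
  if (length(C) != 1L || !is.finite(C) || C <= 0) stop("svr_params: C must be > 0")
  if (length(g) != 1L || !is.finite(g) || g <= 0) stop("svr_params: g must be > 0")
  if (length(eps) != 1L || !is.finite(eps) || eps < 0) {
    stop("svr_params: eps must be >= 0")
  }
  structure(list(C = C, g = g, eps = eps), class = "svr_params")
}

#' Decode an optimizer position into SVR hyperparameters
#'
#' The optimizer searches a 3-D box (default `[0.01, 10]^3`); coordinates map
#' directly to `(C, g, eps)`.
#'
#' @param position numeric vector of length 3.
#' @return an `svr_params` object.
#' @examples
#' decode_position(c(9.849, 0.010, 0.059))
#' @export
decode_position <- function(position) {
  if (length(position) != 3L) stop("decode_position: position must have length 3")
  svr_params(position[1], position[2], position[3])
}

#' RBF coefficient implied by the width parameter g
#'
#' Returns the multiplier `1 / g^2` applied to the squared distance inside
#' the kernel, so `exp(-coef * d2)` equals `exp(-d2 / g^2)` exactly.
#'
#' @param g kernel width, > 0.
#' @return scalar `1 / g^2`.
#' @export
kernel_coefficient <- function(g) {
  if (length(g) != 1L || !is.finite(g) || g <= 0) {
    stop("kernel_coefficient: g must be > 0")
  }
  1 / g^2
}

as_feature_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("non-finite feature values")
  x
}

# Core fit from a precomputed squared-distance matrix (shared by svr_fit and
# the cross-validation objective, where distances are reused across many
# hyperparameter evaluations).
svr_fit_sqdist <- function(D, y, params, tol = 1e-3, max_iter = 50000L) {
  K <- rbf_from_sqdist_cpp(D, kernel_coefficient(params$g))
  svr_smo_cpp(K, y, params$C, params$eps, tol, as.integer(max_iter))
}

#' Fit an epsilon-insensitive RBF support vector regression
#'
#' Solves the SVR dual by sequential minimal optimization (compiled,
#' maximal-violating-pair selection). Inputs are used as given — standardize
#' first for well-scaled problems (see [fit_predict_svr()]).
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y numeric target vector.
#' @param params an [svr_params()] object.
#' @param tol SMO stopping tolerance on the duality-gap bound.
#' @param max_iter cap on SMO pair updates.
#' @return a `barn_svr` model (support coefficients `beta`, `bias`, training
#'   inputs, hyperparameters).
#' @export
svr_fit <- function(x, y, params, tol = 1e-3, max_iter = 50000L) {
  stopifnot(inherits(params, "svr_params"))
  x <- as_feature_matrix(x)
  if (nrow(x) < 2L) stop("svr_fit: need at least 2 training rows")
  if (length(y) != nrow(x)) stop("svr_fit: x and y sizes differ")
  sol <- svr_fit_sqdist(sqdist_cpp(x, x), y, params, tol, max_iter)
  structure(list(beta = sol$beta, bias = sol$bias, x = x, params = params,
                 iterations = sol$iterations, converged = sol$converged),
            class = "barn_svr")
}

#' @export
predict.barn_svr <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  if (nrow(x) == 0L) return(numeric(0))
  if (ncol(x) != ncol(object$x)) stop("predict.barn_svr: feature count mismatch")
  K <- rbf_from_sqdist_cpp(sqdist_cpp(x, object$x),
                           kernel_coefficient(object$params$g))
  drop(K %*% object$beta) + object$bias
}

# Forward-chaining fold boundaries: rows split into folds + 1 contiguous
# blocks; fold i trains on blocks 1..i and validates on block i + 1.
forward_chain_folds <- function(n, folds) {
  if (folds < 2) stop("cv folds must be >= 2")
  if (folds + 1 > n) stop("more cv folds than rows")
  edges <- floor(seq(0, n, length.out = folds + 2))
  lapply(seq_len(folds), function(i) {
    val <- (edges[i + 1] + 1L):edges[i + 2]
    if (length(val) < 2L) stop("cv fold with fewer than 2 validation rows")
    list(train = 1:edges[i + 1], val = val)
  })
}

#' Build the cross-validated fitness the optimizer minimises
#'
#' Returns a closure mapping a 3-D position to the mean RMSE over
#' forward-chaining contiguous time-series folds (train on the earlier
#' blocks, validate on the next block). Squared-distance matrices per fold
#' are precomputed once, so thousands of hyperparameter evaluations only pay
#' for the kernel exponential and the SMO solve. Fully deterministic.
#'
#' @param x standardized feature matrix, rows in time order.
#' @param y standardized target vector.
#' @param folds number of folds (>= 2), default 5.
#' @param tol,max_iter passed to the SMO solver.
#' @return function(position) -> scalar mean validation RMSE.
#' @export
make_cv_objective <- function(x, y, folds = 5, tol = 1e-3, max_iter = 50000L) {
  x <- as_feature_matrix(x)
  stopifnot(length(y) == nrow(x))
  plan <- forward_chain_folds(nrow(x), folds)
  pre <- lapply(plan, function(f) {
    xt <- x[f$train, , drop = FALSE]
    list(D_tt = sqdist_cpp(xt, xt),
         D_vt = sqdist_cpp(x[f$val, , drop = FALSE], xt),
         y_t = y[f$train], y_v = y[f$val])
  })
  function(position) {
    params <- decode_position(position)
    gamma <- kernel_coefficient(params$g)
    rmse <- vapply(pre, function(f) {
      sol <- svr_smo_cpp(rbf_from_sqdist_cpp(f$D_tt, gamma), f$y_t,
                         params$C, params$eps, tol, as.integer(max_iter))
      pred <- drop(rbf_from_sqdist_cpp(f$D_vt, gamma) %*% sol$beta) + sol$bias
      sqrt(mean((f$y_v - pred)^2))
    }, numeric(1))
    mean(rmse)
  }
}

#' Cross-validated RMSE fitness of one hyperparameter triple
#'
#' Convenience wrapper around [make_cv_objective()] for a single evaluation.
#'
#' @param x standardized feature matrix, rows in time order.
#' @param y standardized target vector.
#' @param params an [svr_params()] object.
#' @param folds number of forward-chaining folds, default 5.
#' @return scalar mean validation RMSE.
#' @export
cv_fitness <- function(x, y, params, folds = 5) {
  stopifnot(inherits(params, "svr_params"))
  make_cv_objective(x, y, folds)(c(params$C, params$g, params$eps))
}

#' Fit on training data and predict test inputs in original units
#'
#' Standardizes features and target with parameters fitted on the training
#' rows only, fits the SVR on the standardized scale, and de-standardizes
#' the predictions back to original units.
#'
#' @param train_x,train_y raw training features and target.
#' @param test_x raw test features (may have zero rows).
#' @param params an [svr_params()] object.
#' @return numeric prediction vector in original target units.
#' @export
fit_predict_svr <- function(train_x, train_y, test_x, params) {
  train_x <- as_feature_matrix(train_x)
  test_x <- as_feature_matrix(test_x)
  if (ncol(test_x) != ncol(train_x)) stop("fit_predict_svr: feature mismatch")
  xs <- matrix(0, nrow(train_x), ncol(train_x))
  ts <- matrix(0, nrow(test_x), ncol(test_x))
  for (j in seq_len(ncol(train_x))) {
    s <- standardize(train_x[, j], name = colnames(train_x)[j])
    xs[, j] <- s$values
    if (nrow(test_x) > 0L) ts[, j] <- standardize_apply(test_x[, j], s$params)
  }
  if (max(train_y) - min(train_y) == 0) {   # constant target: nothing to learn
    return(rep(train_y[1], nrow(test_x)))
  }
  sy <- standardize(train_y, name = "target")
  fit <- svr_fit(xs, sy$values, params, tol = 1e-4)  # tight: final-fit path
  if (nrow(test_x) == 0L) return(numeric(0))
  destandardize(predict(fit, ts), sy$params)
}
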