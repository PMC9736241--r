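# Independent oracles, written as plain loops against the printed formulas
# and kept free of the package's own implementation code paths.

# Brute-force split gain: explicit loop transcription of the weighted
# one-side-sampling gain for one threshold.
oracle_split_gain <- function(values, gradients, weights, d) {
  n <- length(values)
  s_left <- 0; s_right <- 0; n_left <- 0; n_right <- 0
  for (i in seq_len(n)) {
    if (values[i] <= d) {
      s_left <- s_left + weights[i] * gradients[i]
      n_left <- n_left + 1
    } else {
      s_right <- s_right + weights[i] * gradients[i]
      n_right <- n_right + 1
    }
  }
  if (n_left == 0 || n_right == 0) return(NA_real_)
  (s_left^2 / n_left + s_right^2 / n_right) / n
}

# Naive grey wolf optimizer: a line-by-line reimplementation of the update
# equations with explicit loops, mirroring the documented RNG draw order
# (wolves initialised one at a time; per wolf, per leader: A then C).
# Greedy improvement-only replacement; coefficients of iteration n use
# schedule index n - 1.
oracle_gwo <- function(objective, lower, upper, M, nmax, seed) {
  set.seed(seed)
  d <- length(lower)
  pos <- matrix(0, M, d)
  fit <- numeric(M)
  for (i in 1:M) {
    pos[i, ] <- lower + runif(d) * (upper - lower)
    fit[i] <- objective(pos[i, ])
  }
  lead <- order(fit)[1:3]
  best_trace <- numeric(nmax)
  for (n in 1:nmax) {
    a <- 2 - 2 * ((n - 1) / nmax)
    leaders <- pos[lead, , drop = FALSE]
    for (i in 1:M) {
      U <- matrix(0, 3, d)
      for (k in 1:3) {
        A <- 2 * a * runif(d) - a
        C <- 2 * runif(d)
        L <- abs(C * leaders[k, ] - pos[i, ])
        U[k, ] <- leaders[k, ] - A * L
      }
      cand <- pmin(pmax((U[1, ] + U[2, ] + U[3, ]) / 3, lower), upper)
      f <- objective(cand)
      if (f < fit[i]) {
        pos[i, ] <- cand
        fit[i] <- f
      }
    }
    lead <- order(fit)[1:3]
    best_trace[n] <- fit[lead[1]]
  }
  list(best_position = pos[lead[1], ], best_fitness = fit[lead[1]],
       best_trace = best_trace)
}

# Standardize with population sd, used when tests need inputs on the scale
# the fitness expects.
std_pop <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
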