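#' Box-constrained search space
#'
#' @param lower,upper numeric vectors of per-dimension bounds,
#'   `lower < upper` elementwise.
#' @return a `search_space` object with fields `lower`, `upper`, `dim`.
#' @examples
#' search_space(rep(0.01, 3), rep(10, 3))
#' @export
search_space <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || length(lower) < 1L) {
    stop("search_space: lower and upper must have equal positive length")
  }
  if (!all(is.finite(lower)) || !all(is.finite(upper)) || !all(lower < upper)) {
    stop("search_space: need finite lower < upper elementwise")
  }
  structure(list(lower = lower, upper = upper, dim = length(lower)),
            class = "search_space")
}

clamp_to_space <- function(x, space) pmin(pmax(x, space$lower), space$upper)

#' Linearly decaying convergence factor a
#'
#' `a = 2 - 2 n / nmax`, decreasing from 2 at the first iteration to 0 at the
#' last. Governs the attack/search balance: the step coefficients A are drawn
#' from `[-a, a]`.
#'
#' @param n current iteration, `0 <= n <= nmax`.
#' @param nmax maximum iteration count, `>= 1`.
#' @return scalar in `[0, 2]`.
#' @export
linear_decay_a <- function(n, nmax) {
  if (length(nmax) != 1L || !is.finite(nmax) || nmax < 1) {
    stop("linear_decay_a: nmax must be >= 1")
  }
  if (any(n < 0) || any(n > nmax)) stop("linear_decay_a: need 0 <= n <= nmax")
  2 - 2 * (n / nmax)
}

#' Random step coefficient vector A
#'
#' Each component is `2 a r1 - a` with `r1 ~ Uniform(0, 1)`, hence in
#' `[-a, a]`. `r1` can be forced for testing.
#'
#' @param a convergence factor in `[0, 2]`.
#' @param dim number of components.
#' @param r1 optional fixed uniform draws (recycled to `dim`).
#' @return numeric vector of length `dim`.
#' @export
coeff_A <- function(a, dim, r1 = NULL) {
  if (a < 0 || a > 2) stop("coeff_A: a must lie in [0, 2]")
  if (is.null(r1)) r1 <- stats::runif(dim)
  2 * a * rep_len(r1, dim) - a
}

#' Deterministic chaotic coefficient schedules
#'
#' The chaotic grey wolf variant replaces the random attraction coefficient C
#' with three deterministic iteration-dependent schedules: a time-varying
#' acceleration constant (C1), a differential-mean perturbed constant (C2)
#' and a sigmoid-scaled quadratic ramp (C3). `sin(n)` takes the integer
#' iteration count in radians. C3 carries a negative factor (0.5 - 2.5) = -2
#' as printed in its source, so C3 <= 0 with C3(nmax) close to -1.
#'
#' @param n current iteration, `0 <= n <= nmax`.
#' @param nmax maximum iteration count, `>= 1`.
#' @return list with scalars `C1`, `C2`, `C3`.
#' @examples
#' chaotic_coefficients(0, 20)   # C1 = 1, C2 = 1, C3 = 0
#' @export
chaotic_coefficients <- function(n, nmax) {
  if (length(nmax) != 1L || !is.finite(nmax) || nmax < 1) {
    stop("chaotic_coefficients: nmax must be >= 1")
  }
  if (n < 0 || n > nmax) stop("chaotic_coefficients: need 0 <= n <= nmax")
  list(
    C1 = 0.5 + 0.5 * exp(-n / 500) + 1.4 * sin(n) / 30,
    C2 = 1 + 1.4 * (1 - exp(-n / 500)) + 1.4 * sin(n) / 30,
    C3 = 1 / (1 + exp(-0.0001 * n / nmax)) * (0.5 - 2.5) * (n / nmax)^2
  )
}

#' One pack-siege position update
#'
#' Moves a wolf toward the three leaders: `L = |C * leader - position|`
#' elementwise, candidate `leader - A * L` per leader, and the update is the
#' mean of the three candidates, clamped to the search space.
#'
#' @param position current wolf position.
#' @param leaders list of three leader positions (alpha, beta, delta).
#' @param A list of three step coefficient vectors (length `dim` each).
#' @param C list of three attraction coefficients (scalars for the chaotic
#'   schedules, vectors for canonical GWO).
#' @param space a `search_space`.
#' @return updated position vector, inside the bounds.
#' @export
update_position <- function(position, leaders, A, C, space) {
  d <- space$dim
  if (length(position) != d) stop("update_position: dimension mismatch")
  u <- matrix(0, nrow = 3, ncol = d)
  for (k in 1:3) {
    lead <- leaders[[k]]
    if (length(lead) != d) stop("update_position: leader dimension mismatch")
    L <- abs(C[[k]] * lead - position)
    u[k, ] <- lead - A[[k]] * L
  }
  clamp_to_space((u[1, ] + u[2, ] + u[3, ]) / 3, space)
}

#' Grey wolf optimization, canonical or chaotic variant
#'
#' Bound-constrained minimisation by a pack of candidate solutions guided by
#' the best three (alpha, beta, delta). Each iteration every wolf proposes a
#' pack-siege update ([update_position()]) with fresh random A vectors; the
#' proposal replaces the wolf only if its fitness improves (greedy accept),
#' then the leaders are refreshed. The `cgwo` variant uses the deterministic
#' schedules of [chaotic_coefficients()] for C; `gwo` draws `C = 2 r2`
#' per dimension. Coefficients used at iteration n are those of schedule
#' index n - 1 (the first update runs with a = 2, C1 = C2 = 1, C3 = 0).
#'
#' @param objective function mapping a position vector to a finite scalar
#'   (lower is better).
#' @param space a `search_space`.
#' @param pack_size number of wolves M, at least 4.
#' @param max_iter iteration count nmax, at least 1.
#' @param variant `"cgwo"` (default) or `"gwo"`.
#' @param seed optional integer seed for reproducibility.
#' @return list with `best_position`, `best_fitness`, `trace` (data.frame
#'   with iteration, best_fitness and alpha position columns), `variant`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- gwo_optimize(sphere, search_space(rep(-5, 3), rep(5, 3)),
#'                     pack_size = 20, max_iter = 50, seed = 1)
#' res$best_fitness
#' @export
gwo_optimize <- function(objective, space, pack_size = 20, max_iter = 20,
                         variant = c("cgwo", "gwo"), seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(space, "search_space"))
  if (pack_size < 4) stop("gwo_optimize: pack_size must be >= 4")
  if (max_iter < 1) stop("gwo_optimize: max_iter must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  d <- space$dim
  eval_fit <- function(x) {
    f <- objective(x)
    if (length(f) != 1L || !is.finite(f)) {
      stop("gwo_optimize: non-finite objective at position (",
           paste(signif(x, 6), collapse = ", "), ")")
    }
    f
  }

  # initialization: one wolf at a time so the RNG draw order is well defined
  pos <- matrix(0, nrow = pack_size, ncol = d)
  fit <- numeric(pack_size)
  for (i in seq_len(pack_size)) {
    pos[i, ] <- space$lower + stats::runif(d) * (space$upper - space$lower)
    fit[i] <- eval_fit(pos[i, ])
  }
  ord <- order(fit)              # ties broken by wolf index (order is stable)
  lead_idx <- ord[1:3]

  trace <- data.frame(iteration = integer(max_iter),
                      best_fitness = numeric(max_iter))
  alpha_trace <- matrix(0, nrow = max_iter, ncol = d)

  for (n in seq_len(max_iter)) {
    n_sched <- n - 1                       # coefficients set before this update
    a <- linear_decay_a(n_sched, max_iter)
    if (variant == "cgwo") {
      cc <- chaotic_coefficients(n_sched, max_iter)
      C_fixed <- list(cc$C1, cc$C2, cc$C3)
    }
    leaders <- list(pos[lead_idx[1], ], pos[lead_idx[2], ], pos[lead_idx[3], ])
    for (i in seq_len(pack_size)) {
      A <- vector("list", 3)
      C <- vector("list", 3)
      for (k in 1:3) {
        A[[k]] <- coeff_A(a, d)
        C[[k]] <- if (variant == "gwo") 2 * stats::runif(d) else C_fixed[[k]]
      }
      cand <- update_position(pos[i, ], leaders, A, C, space)
      f <- eval_fit(cand)
      if (f < fit[i]) {                    # greedy improvement-only accept
        pos[i, ] <- cand
        fit[i] <- f
      }
    }
    ord <- order(fit)
    lead_idx <- ord[1:3]
    trace$iteration[n] <- n
    trace$best_fitness[n] <- fit[lead_idx[1]]
    alpha_trace[n, ] <- pos[lead_idx[1], ]
  }

  colnames(alpha_trace) <- paste0("alpha_", seq_len(d))
  list(best_position = pos[lead_idx[1], ],
       best_fitness = fit[lead_idx[1]],
       trace = cbind(trace, as.data.frame(alpha_trace)),
       variant = variant)
}

#' Write an optimizer trace as CSV
#'
#' @param result a result list from [gwo_optimize()].
#' @param path output file path.
#' @export
write_trace_csv <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
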