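test_that("linear decay factor follows 2 - 2 n/nmax", {
  expect_equal(linear_decay_a(0, 20), 2)
  expect_equal(linear_decay_a(20, 20), 0)
  expect_equal(linear_decay_a(10, 20), 1)
  expect_error(linear_decay_a(1, 0), "nmax")
  expect_error(linear_decay_a(21, 20))
})

test_that("A coefficients are 2 a r1 - a and bounded by a", {
  expect_equal(coeff_A(0, 5), rep(0, 5))
  expect_equal(coeff_A(2, 3, r1 = 1), rep(2, 3))
  expect_equal(coeff_A(1, 1, r1 = 0.25), -0.5)
  set.seed(11)
  for (a in c(0.3, 1.1, 2)) {
    draws <- replicate(50, coeff_A(a, 4))
    expect_true(all(abs(draws) <= a + 1e-12))
  }
  expect_error(coeff_A(2.5, 3), "\\[0, 2\\]")
})

test_that("chaotic schedules match the printed formulas exactly", {
  c0 <- chaotic_coefficients(0, 20)
  expect_identical(c0$C1, 1.0)
  expect_identical(c0$C2, 1.0)
  expect_identical(c0$C3, 0.0)
  # independent transcription of the three schedules
  for (n in c(1, 7, 10, 20)) {
    cc <- chaotic_coefficients(n, 20)
    expect_equal(cc$C1, 0.5 + 0.5 * exp(-n / 500) + 1.4 * sin(n) / 30,
                 tolerance = 1e-14)
    expect_equal(cc$C2, 1 + 1.4 * (1 - exp(-n / 500)) + 1.4 * sin(n) / 30,
                 tolerance = 1e-14)
    expect_equal(cc$C3,
                 (0.5 - 2.5) * (n / 20)^2 / (1 + exp(-0.0001 * n / 20)),
                 tolerance = 1e-14)
  }
  # the sigmoid factor is ~1/2 and the quadratic ramp ends at -2 * 1/2
  expect_equal(chaotic_coefficients(20, 20)$C3, -1.00005, tolerance = 1e-4)
  expect_error(chaotic_coefficients(1, 0), "nmax")
})

test_that("position update reproduces the siege arithmetic", {
  space <- search_space(rep(-10, 2), rep(10, 2))
  p <- c(3, -2)
  same <- list(p, p, p)
  ones <- list(1, 1, 1)
  zeros <- list(rep(0, 2), rep(0, 2), rep(0, 2))
  # leaders at a common point, A = 0, C = 1: wolf lands on the point
  expect_equal(update_position(c(0, 0), same, zeros, ones, space), p)
  # wolf already at the leaders' position: fixed point for any A
  set.seed(4)
  anyA <- list(runif(2, -1, 1), runif(2, -1, 1), runif(2, -1, 1))
  expect_equal(update_position(p, same, anyA, ones, space), p)
  # 1-D hand computation: U = 0, leaders 1, C = 2, A = 0.5 -> 0
  sp1 <- search_space(-5, 5)
  expect_equal(
    update_position(0, list(1, 1, 1), list(0.5, 0.5, 0.5), list(2, 2, 2), sp1),
    0)
  expect_error(update_position(c(1, 2, 3), same, zeros, ones, space),
               "dimension")
})

test_that("optimizer honours contract: determinism, monotone trace, bounds", {
  sphere <- function(x) sum(x^2)
  space <- search_space(rep(-5, 3), rep(5, 3))
  r1 <- gwo_optimize(sphere, space, pack_size = 8, max_iter = 30, seed = 42)
  r2 <- gwo_optimize(sphere, space, pack_size = 8, max_iter = 30, seed = 42)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace$best_fitness) <= 0))
  expect_equal(r1$best_fitness, min(r1$trace$best_fitness))

  # every evaluated position stays inside the box
  seen <- list()
  spy <- function(x) { seen[[length(seen) + 1L]] <<- x; sum(x^2) }
  gwo_optimize(spy, space, pack_size = 6, max_iter = 10, seed = 7,
               variant = "gwo")
  seen <- do.call(rbind, seen)
  expect_true(all(seen >= -5 - 1e-12) && all(seen <= 5 + 1e-12))
})

test_that("flat landscape and invalid configs are handled", {
  space <- search_space(rep(0, 2), rep(1, 2))
  r <- gwo_optimize(function(x) 7, space, pack_size = 5, max_iter = 10,
                    seed = 1)
  expect_equal(r$best_fitness, 7)
  expect_true(all(r$trace$best_fitness == 7))
  expect_error(gwo_optimize(function(x) NaN, space, pack_size = 4,
                            max_iter = 2, seed = 1), "non-finite")
  expect_error(gwo_optimize(function(x) 0, space, pack_size = 3,
                            max_iter = 2), "pack_size")
  expect_error(search_space(c(0, 2), c(1, 1)))
})

test_that("cgwo trace is bit-identical across runs and uses deterministic C", {
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  space <- search_space(rep(-2, 2), rep(2, 2))
  a <- gwo_optimize(rosen, space, pack_size = 10, max_iter = 25, seed = 3)
  b <- gwo_optimize(rosen, space, pack_size = 10, max_iter = 25, seed = 3)
  expect_identical(a$trace$best_fitness, b$trace$best_fitness)
  expect_identical(a$best_position, b$best_position)
})
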