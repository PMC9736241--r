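test_that("one-side sampling keeps top gradients and reweights the rest", {
  set.seed(1)
  s <- goss_sample(c(5, -4, 1, 0), o = 0.5, p = 0.5)
  expect_setequal(s$large_idx, c(1L, 2L))
  expect_length(s$small_idx, 2L)
  expect_true(all(s$small_idx %in% c(3L, 4L)))
  expect_equal(s$weights, c(1, 1, 1, 1))   # (1 - 0.5) / 0.5 = 1

  full <- goss_sample(c(3, 1, 2), o = 1, p = 0)
  expect_setequal(full$large_idx, 1:3)
  expect_length(full$small_idx, 0L)

  ties <- goss_sample(rep(2, 6), o = 0.5, p = 0)
  expect_identical(ties$large_idx, 1:3)    # ties broken by index order

  expect_error(goss_sample(c(1, 2), o = 0.1, p = 0.1), "floor")
})

test_that("split gain matches hand computation and handles degenerate cases", {
  expect_equal(split_gain(c(0, 0, 1, 1), c(1, 1, -1, -1), rep(1, 4), 0), 1)
  expect_equal(split_gain(c(0, 1, 2, 3), rep(0, 4), rep(1, 4), 1.5), 0)
  expect_true(is.na(split_gain(c(1, 2), c(1, 1), c(1, 1), 5)))
})

test_that("split gain agrees with the brute-force oracle on random instances", {
  set.seed(99)
  for (rep in 1:25) {
    n <- 20
    v <- round(runif(n, 0, 10), 2)
    h <- rnorm(n)
    w <- rep(1, n)                         # o = 1: no reweighting
    for (d in sort(unique(v))[-n]) {
      expect_equal(split_gain(v, h, w, d), oracle_split_gain(v, h, w, d),
                   tolerance = 1e-9)
    }
  }
})

test_that("boosting recovers the driving feature", {
  driver_hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    x <- matrix(rnorm(500 * 9), ncol = 9,
                dimnames = list(NULL, paste0("f", 1:9)))
    y <- 2 * x[, "f3"] + rnorm(500, sd = 0.3)
    fit <- fit_goss_gbdt(x, y, goss_config(seed = s))
    if (names(which.max(fit$importance)) == "f3") driver_hits <- driver_hits + 1L
  }
  expect_gte(driver_hits, 9L)
})

test_that("degenerate boosting configurations give zero importance", {
  x <- matrix(rnorm(100), ncol = 2, dimnames = list(NULL, c("a", "b")))
  const <- fit_goss_gbdt(x, rep(3, 50), goss_config(seed = 1))
  expect_length(const$trees, 0L)
  expect_true(all(const$importance == 0))
  none <- fit_goss_gbdt(x, rnorm(50), goss_config(n_trees = 0, seed = 1))
  expect_true(all(none$importance == 0))
  expect_equal(predict(none, x), rep(none$f0, 50))
})

test_that("importance is row-order invariant without sampling", {
  set.seed(5)
  x <- matrix(runif(300), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- x[, 1] - 2 * x[, 2] + rnorm(100, sd = 0.1)
  cfg <- goss_config(o = 1, p = 0, n_trees = 10)
  ref <- fit_goss_gbdt(x, y, cfg)$importance
  perm <- sample(100)
  shuffled <- fit_goss_gbdt(x[perm, ], y[perm], cfg)$importance
  expect_equal(ref, shuffled, tolerance = 1e-9)
})

test_that("top-k selection is ordered, tie-stable and validated", {
  w <- c(co2 = 29.741152, light = 13.195553, air_temp = 13.092886,
         pm25 = 6.540839, h2s = 5.084741, pm10 = 3.862321,
         noise = 3.290505, tsp = 1.477563, nh3 = 0)
  expect_identical(select_features(w, 4), c("co2", "light", "air_temp", "pm25"))
  expect_identical(select_features(w, 9), names(sort(w, decreasing = TRUE)))
  expect_identical(select_features(c(a = 1, b = 2, c = 2), 2), c("b", "c"))
  expect_error(select_features(w, 0), "out of range")
  expect_error(select_features(w, 10), "out of range")
})
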