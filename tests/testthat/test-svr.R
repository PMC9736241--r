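test_that("position decoding and kernel width mapping", {
  p <- decode_position(c(1.000, 0.100, 0.100))
  expect_equal(c(p$C, p$g, p$eps), c(1, 0.1, 0.1))
  p <- decode_position(c(9.849, 0.010, 0.059))
  expect_equal(c(p$C, p$g, p$eps), c(9.849, 0.010, 0.059))
  expect_s3_class(decode_position(c(0.01, 0.01, 0.01)), "svr_params")
  expect_error(decode_position(c(-1, 0.1, 0.1)), "C")
  expect_error(decode_position(c(1, 0.1)), "length 3")

  expect_equal(kernel_coefficient(1), 1)
  expect_equal(kernel_coefficient(10), 0.01)
  expect_equal(kernel_coefficient(0.1), 100)
  expect_error(kernel_coefficient(0), "g")
})

test_that("SMO solution matches scikit-learn's SVR on a shared instance", {
  set.seed(3)
  n <- 60
  x <- matrix(runif(n * 2, -1, 1), ncol = 2)
  y <- sin(2 * pi * x[, 1]) + 0.5 * x[, 2] + rnorm(n, 0, 0.05)
  xt <- matrix(runif(30 * 2, -1, 1), ncol = 2)
  fit <- svr_fit(x, y, svr_params(C = 5, g = 0.5, eps = 0.05), tol = 1e-4)
  ours <- predict(fit, xt)

  dir <- withr::local_tempdir()
  utils::write.csv(data.frame(x, y = y), file.path(dir, "train.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(xt), file.path(dir, "test.csv"),
                   row.names = FALSE)
  script <- c(
    "import sys, numpy as np, pandas as pd",
    "from sklearn.svm import SVR",
    "d = sys.argv[1]",
    "tr = pd.read_csv(d + '/train.csv').values",
    "te = pd.read_csv(d + '/test.csv').values",
    "m = SVR(C=5, gamma=1/0.5**2, epsilon=0.05, tol=1e-4).fit(tr[:, :2], tr[:, 2])",
    "np.savetxt(d + '/pred.csv', m.predict(te))")
  writeLines(script, file.path(dir, "oracle.py"))
  status <- system2("python", c(file.path(dir, "oracle.py"), dir))
  expect_identical(status, 0L)
  theirs <- scan(file.path(dir, "pred.csv"), quiet = TRUE)
  expect_lt(max(abs(ours - theirs)), 0.02)
})

test_that("SVR interpolates noiseless data and handles trivial targets", {
  set.seed(8)
  x <- matrix(runif(120), ncol = 2)
  y <- 3 + 2 * x[, 1] - x[, 2]
  pred <- fit_predict_svr(x, y, x, svr_params(C = 10, g = 0.5, eps = 0.001))
  expect_lt(max(abs(pred - y)), 0.001 + 0.01)

  expect_equal(fit_predict_svr(x, rep(5, 60), x[1:4, ],
                               svr_params(1, 0.1, 0.1)), rep(5, 4))
  expect_identical(fit_predict_svr(x, y, x[0, , drop = FALSE],
                                   svr_params(1, 1, 0.1)), numeric(0))
  x_bad <- x; x_bad[1, 1] <- Inf
  expect_error(fit_predict_svr(x_bad, y, x, svr_params(1, 1, 0.1)),
               "non-finite")
})

test_that("cv fitness separates learnable from unlearnable targets", {
  set.seed(21)
  n <- 200
  x <- matrix(runif(n * 2), ncol = 2)
  y_lin <- std_pop(2 * x[, 1] + x[, 2])
  xs <- apply(x, 2, std_pop)
  fit_lin <- cv_fitness(xs, y_lin, svr_params(C = 10, g = 2, eps = 0))
  expect_lt(fit_lin, 0.05)

  y_noise <- rnorm(n)
  fit_noise <- cv_fitness(xs, std_pop(y_noise), svr_params(1, 0.1, 0.1))
  expect_gt(fit_noise, 0.7)
  expect_lt(fit_noise, 1.3)

  expect_identical(cv_fitness(xs, y_lin, svr_params(2, 1, 0.05)),
                   cv_fitness(xs, y_lin, svr_params(2, 1, 0.05)))
})

test_that("cv fitness is invariant to affine rescaling once standardized", {
  set.seed(22)
  x <- matrix(runif(240), ncol = 2)
  y_raw <- 70 + 4 * x[, 1] + rnorm(120, sd = 0.2)
  xs <- apply(x, 2, std_pop)
  p <- svr_params(3, 1, 0.05)
  # equal up to the SMO stopping tolerance (the sign flip permutes updates)
  expect_equal(cv_fitness(xs, std_pop(y_raw), p),
               cv_fitness(xs, std_pop(5 - 2 * y_raw), p), tolerance = 1e-4)
})

test_that("fold construction is forward chaining", {
  plan <- barncast:::forward_chain_folds(100, 4)
  expect_length(plan, 4L)
  for (f in plan) {
    expect_true(max(f$train) < min(f$val))
    expect_identical(f$train, 1:max(f$train))
  }
  expect_error(barncast:::forward_chain_folds(5, 5), "folds")
})
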