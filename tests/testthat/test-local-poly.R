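test_that("local design matrices have the centered additive form", {
  x <- matrix(c(0, 1, 2), ncol = 1)
  expect_equal(local_design(x, 1, 0), matrix(1, 3, 1))
  z <- local_design(x, 1, 1)
  expect_equal(unname(z), cbind(c(1, 1, 1), c(-1, 0, 1)))
  x2 <- matrix(rnorm(6), ncol = 2)
  expect_equal(ncol(local_design(x2, c(0, 0), 1)), 3) # 1 + p*d
  expect_error(local_design(x, 1, 2), class = "kwlpr_error_degree")
})

test_that("the Nadaraya-Watson fit matches the direct weighted average", {
  # frozen from the independent weighted-average oracle:
  # (K(1)*0 + K(0)*1 + K(1)*4) / (K(1) + K(0) + K(1))
  ds <- make_ds(c(0, 1, 2), y = c(0, 1, 4))
  fit <- kwlpr(ds, degree = 0, kernel = "gaussian", bandwidth = 1)
  # bypass scaling: query on the scaled scale via local_fit
  x0 <- (1 - fit$scaler$mean[1]) / fit$scaler$sd[1]
  h_scaled <- 1 / fit$scaler$sd[1]
  fit_raw <- kwlpr(ds, degree = 0, kernel = "gaussian",
                   bandwidth = h_scaled)
  lf <- local_fit(fit_raw, x0)
  expect_equal(lf$prediction, 1.5481372, tolerance = 1e-6)
  k <- dnorm(c(1, 0, 1))
  expect_equal(lf$prediction, sum(k * c(0, 1, 4)) / sum(k), tolerance = 1e-12)
  expect_equal(lf$prediction, unname(lf$beta[1]))
})

test_that("a single positively weighted point is predicted exactly", {
  tab <- data.frame(x = c(2, 2, 2.5), y = c(5, 5, 5),
                    split = c("train", "train", "train"))
  # single distinct training value handled through the one-point contract:
  # any query with positive weight returns the weighted mean of y = 5
  ds <- suppressWarnings(kw_dataset(tab, response = "y", descriptors = "x",
                                    split = "split"))
  fit <- kwlpr(ds, degree = 0, kernel = "gaussian", bandwidth = 1)
  expect_equal(unname(predict(fit, data.frame(x = c(1.9, 2.2)))), c(5, 5))
})

test_that("local-linear reproduces affine truths for every kernel/bandwidth", {
  set.seed(21)
  x <- matrix(runif(60, -2, 2), ncol = 2)
  y <- 3 - 1.5 * x[, 1] + 0.8 * x[, 2]
  ds <- make_ds(x, y)
  xq <- as.data.frame(matrix(runif(20, -1.5, 1.5), ncol = 2))
  names(xq) <- c("d1", "d2")
  truth <- 3 - 1.5 * xq$d1 + 0.8 * xq$d2
  for (k in c("gaussian", "epanechnikov", "uniform")) {
    for (h in c(0.3, 1, 3)) {
      fit <- kwlpr(ds, degree = 1, kernel = k, bandwidth = c(h, h))
      pred <- tryCatch(predict(fit, xq), error = function(e) NULL)
      if (is.null(pred)) next # compact kernel, empty neighborhood: skip combo
      expect_equal(unname(pred), truth, tolerance = 1e-8,
                   info = paste(k, h))
    }
  }
})

test_that("h -> infinity recovers the global mean (lc) and global OLS (ll)", {
  ds <- generate_fixture("qsaar2d", n_train = 40, n_valid = 10, seed = 8)
  fit0 <- kwlpr(ds, degree = 0, kernel = "gaussian", bandwidth = c(1e6, 1e6))
  preds <- predict(fit0)
  expect_equal(unname(preds), rep(mean(fit0$y_train), nrow(ds)),
               tolerance = 1e-6)

  # uniform kernel with everything inside support: exactly the mean
  fitu <- kwlpr(ds, degree = 0, kernel = "uniform", bandwidth = c(100, 100))
  expect_equal(unname(predict(fitu)), rep(mean(fitu$y_train), nrow(ds)),
               tolerance = 1e-12)

  fit1 <- kwlpr(ds, degree = 1, kernel = "gaussian", bandwidth = c(1e6, 1e6))
  scaled <- scale_descriptors(ds, fit1$scaler)
  tr <- scaled[scaled$split == "train", ]
  ols <- lm(pLC50 ~ LogP + pEC50, data = tr)
  expect_equal(unname(predict(fit1)),
               unname(predict(ols, scaled)), tolerance = 1e-6)
})

test_that("local fits agree with the explicit normal-equation oracle", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(5:20, 1)
    d <- sample(1:3, 1)
    degree <- sample(0:1, 1)
    kernel <- sample(c("gaussian", "epanechnikov", "uniform"), 1)
    x <- matrix(rnorm(n * d), ncol = d)
    y <- rnorm(n)
    h <- runif(d, 0.8, 2.5)
    ds <- make_ds(x, y)
    fit <- kwlpr(ds, degree = degree, kernel = kernel, bandwidth = h)
    x0 <- rnorm(d) * 0.5
    w <- oracle_weights(fit$x_train, x0, h, kernel)
    if (sum(w > 0) < (1 + degree * d) + 1) next
    expected <- oracle_local_fit(fit$x_train, y, x0, degree, h, kernel)
    got <- local_fit(fit, x0)
    expect_equal(unname(got$beta), expected, tolerance = 1e-8,
                 info = paste(rep, kernel, degree))
  }
})

test_that("Nadaraya-Watson predictions are convex combinations of y", {
  set.seed(7)
  for (k in c("gaussian", "epanechnikov", "uniform")) {
    x <- matrix(rnorm(60), ncol = 2)
    y <- rnorm(30)
    ds <- make_ds(x, y)
    fit <- kwlpr(ds, degree = 0, kernel = k, bandwidth = c(1.2, 1.2))
    xq <- as.data.frame(matrix(rnorm(40) * 0.8, ncol = 2))
    names(xq) <- c("d1", "d2")
    pred <- predict(fit, xq)
    expect_true(all(pred >= min(y) - 1e-12 & pred <= max(y) + 1e-12),
                info = k)
  }
})

test_that("training-row order never changes predictions", {
  set.seed(13)
  x <- matrix(rnorm(40), ncol = 2)
  y <- rnorm(20)
  xq <- as.data.frame(matrix(rnorm(10), ncol = 2))
  names(xq) <- c("d1", "d2")
  perm <- sample(20)
  for (degree in 0:1) {
    f1 <- kwlpr(make_ds(x, y), degree = degree, bandwidth = c(0.8, 0.8))
    f2 <- kwlpr(make_ds(x[perm, ], y[perm]), degree = degree,
                bandwidth = c(0.8, 0.8))
    expect_equal(predict(f1, xq), predict(f2, xq), tolerance = 1e-10)
  }
})

test_that("empty neighborhoods raise an explicit, advisory error", {
  ds <- make_ds(c(0, 0.1, 0.2, 1, 1.1), y = 1:5)
  fit <- kwlpr(ds, degree = 0, kernel = "uniform", bandwidth = 0.05)
  err <- expect_error(predict(fit, data.frame(d1 = 10)),
                      class = "kwlpr_error_empty_neighborhood")
  expect_match(conditionMessage(err), "bandwidth|Gaussian")
  # the gaussian kernel keeps the neighborhood non-empty under the same
  # moderate extrapolation
  fitg <- kwlpr(ds, degree = 0, kernel = "gaussian", bandwidth = 1)
  expect_silent(predict(fitg, data.frame(d1 = 10)))
})

test_that("tiny gaussian bandwidths interpolate the training responses", {
  set.seed(3)
  x <- seq(0, 1, length.out = 8)
  y <- rnorm(8)
  ds <- make_ds(x, y)
  fit <- kwlpr(ds, degree = 0, kernel = "gaussian", bandwidth = 0.01)
  expect_equal(unname(predict(fit, data.frame(d1 = x))), y, tolerance = 1e-6)
})
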