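sine_xy <- function(n, seed = 1, noise = sqrt(0.5) / 3) {
  set.seed(seed)
  x <- matrix(sort(runif(n, 0, 2 * pi)), ncol = 1)
  list(x = x, y = sin(x[, 1]) + rnorm(n, 0, noise))
}

test_that("the LSCV objective equals literal leave-one-out refitting", {
  d <- sine_xy(20, seed = 2)
  for (degree in 0:1) {
    # degree 1 starts at 0.3: below that the left-out local systems turn
    # near-singular and the comparison would measure solver conditioning,
    # not the objective
    grid <- exp(seq(log(if (degree == 0) 0.05 else 0.3), log(3),
                    length.out = 30))
    for (h in grid) {
      got <- lscv_objective(d$x, d$y, h, degree = degree, kernel = "gaussian")
      want <- oracle_lscv(d$x, d$y, degree, h, "gaussian")
      expect_equal(got, want, tolerance = 1e-10, info = paste(degree, h))
    }
  }
  # shortcut and refit paths agree inside the package too
  for (h in c(0.2, 0.8)) {
    expect_equal(
      lscv_objective(d$x, d$y, h, 1, "gaussian", method = "shortcut"),
      lscv_objective(d$x, d$y, h, 1, "gaussian", method = "refit"),
      tolerance = 1e-10
    )
  }
})

test_that("two-point LSCV is the squared cross-prediction error", {
  # each LOO prediction is the other point's response
  x <- matrix(c(0, 1), ncol = 1)
  y <- c(0, 1)
  for (h in c(0.1, 1, 10)) {
    expect_equal(lscv_objective(x, y, h, degree = 0, kernel = "gaussian"), 1)
  }
  # pure function: same h, same value
  d <- sine_xy(15, seed = 3)
  v1 <- lscv_objective(d$x, d$y, 0.4, 0, "gaussian")
  v2 <- lscv_objective(d$x, d$y, 0.4, 0, "gaussian")
  expect_identical(v1, v2)
})

test_that("AICc has the documented limits and overfit barrier", {
  d <- sine_xy(25, seed = 4)
  # huge bandwidth: tr(H) -> 1, sigma2 -> variance about the mean
  a <- aicc_objective(d$x, d$y, 1e6, degree = 0, kernel = "gaussian")
  expected <- log(mean((d$y - mean(d$y))^2)) + (1 + 1 / 25) / (1 - 3 / 25)
  expect_equal(a, expected, tolerance = 1e-4)
  expect_true(is.finite(a))
  # tiny bandwidth: every point dominates its own fit, tr(H) -> n
  expect_identical(aicc_objective(d$x, d$y, 1e-4, 0, "gaussian"), Inf)
  # interior minimum between the overfit and oversmooth regimes
  grid <- exp(seq(log(0.05), log(5), length.out = 25))
  vals <- vapply(grid, function(h) aicc_objective(d$x, d$y, h, 0, "gaussian"),
                 numeric(1))
  finite <- which(is.finite(vals))
  k <- finite[which.min(vals[finite])]
  expect_gt(k, 1)
  expect_lt(k, length(grid))
})

test_that("selection finds the grid minimizer and is seed-deterministic", {
  d <- sine_xy(30, seed = 5)
  sel <- select_bandwidth(d$x, d$y, degree = 0, kernel = "gaussian",
                          method = "cv.ls", seed = 1)
  grid <- exp(seq(log(0.05), log(5), length.out = 200))
  vals <- vapply(grid, function(h) lscv_objective(d$x, d$y, h, 0, "gaussian"),
                 numeric(1))
  h_grid <- grid[which.min(vals)]
  # optimizer at least matches the dense grid, up to local refinement
  expect_lte(sel$objective_value, min(vals) + 1e-8)
  expect_equal(sel$selected, h_grid, tolerance = 0.1)
  # objective_value is the objective re-evaluated at the selection
  expect_equal(sel$objective_value,
               lscv_objective(d$x, d$y, sel$selected, 0, "gaussian"),
               tolerance = 1e-12)

  sel2 <- select_bandwidth(d$x, d$y, degree = 0, kernel = "gaussian",
                           method = "cv.ls", seed = 1)
  expect_identical(sel, sel2)
  expect_true(all(sel$selected >= 0.05 & sel$selected <= 5))
})

test_that("selected bandwidths beat 10x over- and under-smoothing out of sample", {
  d <- sine_xy(60, seed = 6)
  holdout <- sine_xy(60, seed = 61)
  sel <- select_bandwidth(d$x, d$y, degree = 0, kernel = "gaussian",
                          method = "cv.ls", seed = 1)
  ds <- make_ds(d$x, d$y)
  rmse_at <- function(h) {
    fit <- kwlpr(ds, degree = 0, kernel = "gaussian",
                 bandwidth = h / sd(d$x))
    sqrt(mean((holdout$y - predict(fit, data.frame(d1 = holdout$x[, 1])))^2))
  }
  h <- sel$selected
  expect_lt(rmse_at(h), rmse_at(h / 10))
  expect_lt(rmse_at(h), rmse_at(min(10 * h, 50)))
})

test_that("in-sample fit tightens as h shrinks while LOO error does not", {
  d <- sine_xy(50, seed = 7)
  ds <- make_ds(d$x, d$y)
  grid <- exp(seq(log(0.05), log(5), length.out = 12))
  rmse_c <- vapply(grid, function(h) {
    fit <- kwlpr(ds, degree = 0, kernel = "gaussian", bandwidth = h / sd(d$x))
    glance(fit)$rmse_c
  }, numeric(1))
  # calibration error non-decreasing in h (small h overfits)
  expect_true(all(diff(rmse_c) >= -1e-8))
  cv <- vapply(grid, function(h) {
    lscv_objective(d$x, d$y, h, 0, "gaussian")
  }, numeric(1))
  # LOO error has an interior minimum: neither endpoint wins
  expect_gt(which.min(cv), 1)
  expect_lt(which.min(cv), length(grid))
})

test_that("the plug-in selector behaves like the asymptotic formula", {
  # quadratic truth on [0,1] with known noise: compare to the closed-form
  # optimal-rate bandwidth h^5 = R(K) sigma^2 / (n mu2^2 theta22)
  set.seed(42)
  n <- 50
  x <- runif(n)
  sigma <- 0.1
  y <- x^2 + rnorm(n, 0, sigma)
  h_opt <- ((1 / (2 * sqrt(pi))) * sigma^2 / (n * 4))^(1 / 5)
  h <- plugin_bandwidth(x, y)
  expect_gt(h, h_opt / 2)
  expect_lt(h, h_opt * 2)

  # deterministic: identical reruns bit for bit
  expect_identical(h, plugin_bandwidth(x, y))

  # exactly linear response: curvature functional ~ 0 drives h to the
  # upper bound with a warning
  y_lin <- 2 * x + 1
  expect_warning(h_lin <- plugin_bandwidth(x, y_lin),
                 class = "kwlpr_warning_plugin_degenerate")
  expect_equal(h_lin, 5)

  expect_error(plugin_bandwidth(cbind(x, x^3), y),
               class = "kwlpr_error_unsupported")
  expect_error(select_bandwidth(cbind(x, x^3), y, degree = 1,
                                method = "plugin"),
               class = "kwlpr_error_unsupported")
  expect_error(select_bandwidth(matrix(x, ncol = 1), y, degree = 0,
                                method = "plugin"),
               class = "kwlpr_error_unsupported")
})
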