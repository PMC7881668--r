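#' Fit a kernel-weighted local polynomial regression model
#'
#' The workhorse of the package. At every query point \eqn{x_0} a polynomial
#' of degree \eqn{p} is fitted by weighted least squares, with weights from a
#' product kernel over the auto-scaled descriptors:
#' \deqn{\min_\beta \sum_i \{y_i - \sum_j \beta_j (x_i - x_0)^j\}^2
#'       K\{(x_i - x_0)/h\}}
#' whose solution is \eqn{\hat\beta = (X^T W X)^{-1} X^T W y}; the local
#' intercept \eqn{\hat\beta_0} is the prediction. Two estimators are
#' supported: the local-constant (Nadaraya-Watson) estimator (`degree = 0`,
#' a kernel-weighted average) and the local-linear estimator (`degree = 1`,
#' additive first-order terms, one slope per descriptor). Higher degrees are
#' deliberately not offered: low-order local polynomials extrapolate far more
#' reliably, which matters when predicting new compounds near the edge of the
#' training domain.
#'
#' Descriptors are auto-scaled with training-split statistics before any
#' weighting, and bandwidths are interpreted on that scaled scale. If
#' `bandwidth` is `NULL` it is selected automatically; see
#' [select_bandwidth()].
#'
#' The normal equations are solved by a ridge-stabilized direct solve: when
#' \eqn{X^T W X} is singular or near-singular (sparse neighborhoods with the
#' local-linear estimator), `ridge` times the mean diagonal of \eqn{X^T W X}
#' is added before retrying. A query where every weight is zero (compact
#' kernel, empty neighborhood) raises an error suggesting a larger bandwidth
#' or the Gaussian kernel.
#'
#' @param data A `kw_dataset`, or a data frame accompanied by the
#'   `response`/`descriptors`/`id`/`split` role arguments of [kw_dataset()].
#' @inheritParams kw_dataset
#' @param degree Local polynomial degree: `0` (local-constant, `"lc"`) or `1`
#'   (local-linear, `"ll"`). The strings `"lc"`/`"ll"` are also accepted.
#' @param kernel Kernel name; see [kernel_value()].
#' @param bandwidth Numeric vector of per-descriptor bandwidths on the scaled
#'   scale, or `NULL` to select them with `bw_method`.
#' @param bw_method Bandwidth selection method when `bandwidth` is `NULL`:
#'   `"cv.ls"` (least-squares cross-validation), `"cv.aic"` (corrected-AIC
#'   cross-validation) or `"plugin"` (direct plug-in; univariate local-linear
#'   only).
#' @param bw_bounds Length-2 search bounds for bandwidth selection.
#' @param n_restarts Number of optimizer starts for bandwidth selection.
#' @param seed Integer seed making bandwidth selection reproducible.
#' @param ridge Relative ridge term for the singularity fallback.
#' @return An object of class `kwlpr`. Use [predict()][predict.kwlpr()],
#'   [kw_validate()], [williams_table()], [y_scramble()] and
#'   [glance()][glance.kwlpr()] on it.
#' @examples
#' ds <- generate_fixture("sine1d", seed = 1)
#' fit <- kwlpr(ds, degree = 0, kernel = "gaussian", bandwidth = 0.3)
#' head(predict(fit))
#' @export
kwlpr <- function(data, response = NULL, descriptors = NULL, id = NULL,
                  split = NULL, degree = 0,
                  kernel = c("gaussian", "epanechnikov", "uniform"),
                  bandwidth = NULL,
                  bw_method = c("cv.ls", "cv.aic", "plugin"),
                  bw_bounds = c(0.05, 5), n_restarts = 5, seed = 1,
                  ridge = 1e-8) {
  kernel <- match.arg(kernel)
  bw_method <- match.arg(bw_method)
  degree <- normalize_degree(degree)

  if (!inherits(data, "kw_dataset")) {
    if (is.null(response)) {
      abort_kw("Supply a kw_dataset or a `response` column name.",
               "kwlpr_error_schema")
    }
    data <- kw_dataset(data, response = response, descriptors = descriptors,
                       id = id, split = split)
  }
  roles <- kw_roles(data)
  scaler <- fit_scaler(data)
  scaled <- scale_descriptors(data, scaler)
  train <- scaled[scaled$split == "train", ]
  x_train <- descriptor_matrix(train, roles$descriptors)
  y_train <- train[[roles$response]]

  selection <- NULL
  if (is.null(bandwidth)) {
    selection <- select_bandwidth(
      x_train, y_train, degree = degree, kernel = kernel, method = bw_method,
      bounds = bw_bounds, n_restarts = n_restarts, seed = seed, ridge = ridge
    )
    bandwidth <- selection$selected
  }
  bandwidth <- as.numeric(bandwidth)
  if (length(bandwidth) == 1 && ncol(x_train) > 1) {
    bandwidth <- rep(bandwidth, ncol(x_train))
  }
  if (length(bandwidth) != ncol(x_train)) {
    abort_kw("`bandwidth` must have one entry per descriptor.",
             "kwlpr_error_bandwidth")
  }
  check_bandwidth(bandwidth)
  names(bandwidth) <- roles$descriptors

  structure(
    list(
      dataset = data,
      roles = roles,
      scaler = scaler,
      x_train = x_train,
      y_train = y_train,
      train_ids = train$compound_id,
      degree = degree,
      kernel = kernel,
      bandwidth = bandwidth,
      selection = selection,
      ridge = ridge
    ),
    class = "kwlpr"
  )
}

normalize_degree <- function(degree) {
  if (is.character(degree)) {
    degree <- switch(tolower(degree),
      lc = 0L, ll = 1L,
      abort_kw("`degree` must be 0, 1, 'lc' or 'll'.", "kwlpr_error_degree")
    )
  }
  degree <- as.integer(degree)
  if (!degree %in% c(0L, 1L)) {
    abort_kw("Only degrees 0 (local-constant) and 1 (local-linear) are supported.",
             "kwlpr_error_degree")
  }
  degree
}

#' Local design matrix centered at a query point
#'
#' Degree 0 gives a single column of ones; degree 1 appends the centered
#' descriptor columns \eqn{x_{ij} - x_{0j}} (additive first-order terms, no
#' cross terms), for `1 + degree * d` columns in total.
#'
#' @param x Numeric matrix of (scaled) descriptors.
#' @param x0 Query point, length `ncol(x)`.
#' @param degree Local polynomial degree, 0 or 1.
#' @return The local design matrix with `nrow(x)` rows.
#' @export
local_design <- function(x, x0, degree) {
  x <- as.matrix(x)
  degree <- normalize_degree(degree)
  if (degree == 0L) {
    matrix(1, nrow(x), 1)
  } else {
    cbind(1, sweep(x, 2, as.numeric(x0)))
  }
}

# Weighted least-squares solve of the local normal equations with a
# ridge-stabilized retry. Returns beta and the (1,1) element of the inverse
# normal matrix (needed for the smoother diagonal).
solve_local_wls <- function(z, w, y, ridge) {
  zw <- z * w
  a <- crossprod(zw, z)
  b <- crossprod(zw, y)
  sol <- tryCatch(solve(a, cbind(b, diag(ncol(a))[, 1])),
                  error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol))) {
    lambda <- ridge * mean(diag(a))
    if (!is.finite(lambda) || lambda <= 0) lambda <- ridge
    a2 <- a + diag(lambda, ncol(a))
    sol <- tryCatch(solve(a2, cbind(b, diag(ncol(a))[, 1])),
                    error = function(e) NULL)
    if (is.null(sol) || !all(is.finite(sol))) {
      abort_kw("Local normal equations are singular even after the ridge fallback.",
               "kwlpr_error_singular")
    }
  }
  list(beta = sol[, 1], ainv_e1 = sol[, 2])
}

#' Fit the local polynomial at one (scaled) query point
#'
#' Exposes a single local weighted least-squares fit: the coefficient vector
#' \eqn{\hat\beta}, whose first element is the prediction, and the total
#' kernel weight of the neighborhood.
#'
#' @param model A fitted `kwlpr` object.
#' @param x0 Query point on the scaled descriptor scale, length `d`.
#' @return A list with `beta` (named coefficient vector), `prediction`
#'   (`beta[1]`) and `weight_sum`.
#' @export
local_fit <- function(model, x0) {
  stopifnot(inherits(model, "kwlpr"))
  x0 <- as.numeric(x0)
  w <- product_weights(model$x_train, x0, model$bandwidth, model$kernel)
  sw <- sum(w)
  if (sw <= 0) {
    abort_kw(
      paste0("Empty neighborhood at the query point: all kernel weights are zero. ",
             "Increase the bandwidth or use the Gaussian kernel."),
      "kwlpr_error_empty_neighborhood"
    )
  }
  if (model$degree == 0L) {
    beta <- c(`(Intercept)` = sum(w * model$y_train) / sw)
  } else {
    z <- local_design(model$x_train, x0, 1L)
    fit <- solve_local_wls(z, w, model$y_train, model$ridge)
    beta <- stats::setNames(fit$beta,
                            c("(Intercept)", model$roles$descriptors))
  }
  list(beta = beta, prediction = unname(beta[1]), weight_sum = sw)
}

# Vectorized predictions for scaled query rows against scaled training data.
# Returns list(pred, hat) where hat[i] is the weight observation i gives its
# own fitted value -- only meaningful when xq and xt are the same matrix
# (in-sample smoother diagonal); NA otherwise.
kw_predict_scaled <- function(xq, xt, y, degree, bandwidth, kernel, ridge,
                              hat = FALSE) {
  w <- weight_matrix(xq, xt, bandwidth, kernel)
  m <- nrow(xq)
  pred <- rep(NA_real_, m)
  hat_diag <- if (hat) rep(NA_real_, m) else NULL
  if (degree == 0L) {
    sw <- rowSums(w)
    ok <- sw > 0
    pred[ok] <- (w %*% y)[ok] / sw[ok]
    if (hat) hat_diag[ok] <- diag(w)[ok] / sw[ok]
  } else {
    for (i in seq_len(m)) {
      wi <- w[i, ]
      if (sum(wi) <= 0) next
      z <- cbind(1, sweep(xt, 2, xq[i, ]))
      fit <- tryCatch(solve_local_wls(z, wi, y, ridge),
                      error = function(e) NULL)
      if (is.null(fit)) next
      pred[i] <- fit$beta[1]
      if (hat) {
        # query i coincides with training row i, so its centered design row
        # is e1 and the smoother diagonal reduces to w_ii * (A^-1)[1,1]
        hat_diag[i] <- wi[i] * fit$ainv_e1[1]
      }
    }
  }
  list(pred = pred, hat = hat_diag)
}

#' Predict responses for new compounds
#'
#' Applies the model's auto-scaling to the new descriptor values and performs
#' one local weighted least-squares fit per row. Predictions are returned in
#' response units and are deterministic.
#'
#' @param object A fitted `kwlpr` model.
#' @param newdata A data frame with the model's descriptor columns in raw
#'   (unscaled) units. Default: the full dataset the model was built from
#'   (training and validation rows).
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row of `newdata`.
#' @export
predict.kwlpr <- function(object, newdata = NULL, ...) {
  newdata <- newdata %||% object$dataset
  miss <- setdiff(object$roles$descriptors, names(newdata))
  if (length(miss)) {
    abort_kw(sprintf("newdata is missing descriptor column(s): %s.",
                     paste(miss, collapse = ", ")),
             "kwlpr_error_schema")
  }
  scaled <- scale_descriptors(tibble::as_tibble(newdata), object$scaler)
  xq <- descriptor_matrix(scaled, object$roles$descriptors)
  res <- kw_predict_scaled(xq, object$x_train, object$y_train, object$degree,
                           object$bandwidth, object$kernel, object$ridge)
  if (anyNA(res$pred)) {
    bad <- which(is.na(res$pred))
    abort_kw(
      sprintf(
        "Empty neighborhood for %d query row(s) (first: row %d): all kernel weights are zero. Increase the bandwidth or use the Gaussian kernel.",
        length(bad), bad[1]
      ),
      "kwlpr_error_empty_neighborhood"
    )
  }
  res$pred
}

#' @export
print.kwlpr <- function(x, ...) {
  est <- if (x$degree == 0L) "local-constant (Nadaraya-Watson)" else "local-linear"
  cat("Kernel-weighted local polynomial regression\n")
  cat(sprintf("  estimator: %s, kernel: %s\n", est, x$kernel))
  cat(sprintf("  training compounds: %d, descriptors: %d\n",
              length(x$y_train), ncol(x$x_train)))
  cat("  bandwidths (scaled scale):\n")
  for (d in names(x$bandwidth)) {
    cat(sprintf("    %s: %.3f\n", d, x$bandwidth[[d]]))
  }
  if (!is.null(x$selection)) {
    cat(sprintf("  selected by %s (objective %.6g)\n",
                x$selection$method, x$selection$objective_value))
  }
  invisible(x)
}
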