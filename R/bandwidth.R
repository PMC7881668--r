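#' Least-squares cross-validation objective
#'
#' \eqn{CV(h) = n^{-1} \sum_i \{y_i - \hat m_{-i}(x_i)\}^2}, the mean squared
#' leave-one-out (LOO) prediction error over the training rows. For the two
#' supported linear smoothers the LOO prediction is obtained exactly from the
#' in-sample fit and the smoother diagonal,
#' \eqn{\hat m_{-i}(x_i) = (\hat m(x_i) - H_{ii} y_i)/(1 - H_{ii})}; a
#' literal refit-per-left-out-point path (`method = "refit"`) is provided as
#' an independent check. Rows whose leave-one-out neighborhood is empty (the
#' remaining weights are all zero, or the point carries all the weight of its
#' own fit) contribute a large finite penalty of four times the response
#' variance, keeping the objective total so optimizers never see an error.
#'
#' @param x Numeric matrix of scaled training descriptors.
#' @param y Numeric training response.
#' @param bandwidth Per-descriptor bandwidth vector on the scaled scale.
#' @param degree Local polynomial degree, 0 or 1 (or `"lc"`/`"ll"`).
#' @param kernel Kernel name; see [kernel_value()].
#' @param method `"shortcut"` (hat-diagonal identity, default) or `"refit"`
#'   (literal leave-one-out refitting).
#' @param ridge Relative ridge term for the singularity fallback.
#' @return The scalar objective value (non-negative, finite).
#' @export
lscv_objective <- function(x, y, bandwidth, degree = 0, kernel = "gaussian",
                           method = c("shortcut", "refit"), ridge = 1e-8) {
  method <- match.arg(method)
  degree <- normalize_degree(degree)
  x <- as.matrix(x)
  check_bandwidth(bandwidth)
  loo <- kw_loo_predict(x, y, degree, bandwidth, kernel, ridge, method)
  penalty <- 4 * stats::var(y)
  sq <- ifelse(is.na(loo), penalty, (y - loo)^2)
  mean(sq)
}

# leave-one-out predictions over the training rows; NA marks rows whose LOO
# neighborhood is empty or degenerate
kw_loo_predict <- function(x, y, degree, bandwidth, kernel, ridge,
                           method = "shortcut") {
  n <- length(y)
  refit_one <- function(i) {
    res <- tryCatch(
      kw_predict_scaled(x[i, , drop = FALSE], x[-i, , drop = FALSE],
                        y[-i], degree, bandwidth, kernel, ridge),
      error = function(e) list(pred = NA_real_)
    )
    res$pred
  }
  if (method == "shortcut") {
    fit <- kw_predict_scaled(x, x, y, degree, bandwidth, kernel, ridge,
                             hat = TRUE)
    denom <- 1 - fit$hat
    loo <- (fit$pred - fit$hat * y) / denom
    # the deletion identity degenerates when a point carries (numerically)
    # all of its own fit; those rows are refitted literally
    bad <- which(!is.finite(loo) | !is.finite(denom) | denom <= 1e-4)
    for (i in bad) loo[i] <- refit_one(i)
    loo
  } else {
    vapply(seq_len(n), refit_one, numeric(1))
  }
}

#' Corrected-AIC (expected Kullback-Leibler) cross-validation objective
#'
#' The Hurvich-Simonoff-Tsai corrected AIC for linear smoothers:
#' \deqn{AIC_c(h) = \log\hat\sigma^2 +
#'   \frac{1 + tr(H)/n}{1 - (tr(H) + 2)/n}}
#' with \eqn{\hat\sigma^2 = n^{-1}\sum_i \{y_i - \hat m(x_i)\}^2} and
#' \eqn{H} the smoother (hat) matrix mapping the response to the in-sample
#' fitted values. Returns `+Inf` when \eqn{tr(H) + 2 \ge n} (the overfitting
#' barrier) or when any in-sample neighborhood is empty.
#'
#' @inheritParams lscv_objective
#' @return The scalar objective value; may be `+Inf`.
#' @export
aicc_objective <- function(x, y, bandwidth, degree = 0, kernel = "gaussian",
                           ridge = 1e-8) {
  degree <- normalize_degree(degree)
  x <- as.matrix(x)
  check_bandwidth(bandwidth)
  n <- length(y)
  fit <- kw_predict_scaled(x, x, y, degree, bandwidth, kernel, ridge,
                           hat = TRUE)
  if (anyNA(fit$pred) || anyNA(fit$hat)) return(Inf)
  tr_h <- sum(fit$hat)
  if (tr_h + 2 >= n) return(Inf)
  sigma2 <- mean((y - fit$pred)^2)
  if (sigma2 <= 0) return(-Inf)
  log(sigma2) + (1 + tr_h / n) / (1 - (tr_h + 2) / n)
}

#' Direct plug-in bandwidth for univariate local-linear regression
#'
#' Deterministic, optimization-free bandwidth selection for the univariate
#' local-linear estimator with a Gaussian kernel: pilot blocked-quartic fits
#' estimate the integrated squared second derivative and the residual
#' variance, which are plugged into the asymptotically optimal bandwidth
#' formula (Ruppert-Sheather-Wand direct plug-in, via
#' [KernSmooth::dpill()]). When the curvature functional degenerates (e.g. an
#' exactly linear relationship) the bandwidth is clamped to the upper search
#' bound with a warning.
#'
#' @param x Numeric vector: the single scaled descriptor.
#' @param y Numeric response.
#' @param bounds Length-2 clamp interval for the returned bandwidth.
#' @return A length-1 named-free bandwidth.
#' @export
plugin_bandwidth <- function(x, y, bounds = c(0.05, 5)) {
  x <- as.matrix(x)
  if (ncol(x) > 1) {
    abort_kw(
      "The direct plug-in method is univariate only; use cv.ls or cv.aic for multiple descriptors.",
      "kwlpr_error_unsupported"
    )
  }
  h <- tryCatch(
    suppressWarnings(KernSmooth::dpill(as.numeric(x), y)),
    error = function(e) NA_real_
  )
  if (!is.finite(h) || h <= 0) {
    rlang::warn(
      "Plug-in pilot estimate degenerated (curvature ~ 0); returning the upper bandwidth bound.",
      class = "kwlpr_warning_plugin_degenerate"
    )
    return(bounds[2])
  }
  min(max(h, bounds[1]), bounds[2])
}

#' Automatic data-driven bandwidth selection
#'
#' Selects one constant bandwidth per descriptor by bounded multistart
#' minimization of the chosen objective over the bandwidth box, on the log
#' scale. The first start is the geometric center of the box; the remaining
#' `n_restarts - 1` starts are drawn uniformly in the log box from `seed`, so
#' the result is a pure function of (data, method, bounds, n_restarts, seed).
#' Both box corners are also evaluated; if no optimizer run improves on them
#' a warning is raised and the best point found is returned.
#'
#' @inheritParams lscv_objective
#' @param method `"cv.ls"` (least-squares CV), `"cv.aic"` (corrected-AIC CV)
#'   or `"plugin"` (univariate local-linear only).
#' @param bounds Length-2 positive search bounds, on the scaled scale.
#' @param n_restarts Number of optimizer starts (>= 1).
#' @param seed Integer seed for the restart draws.
#' @return A list of class `kw_bwsel`: `method`, `selected` (bandwidth
#'   vector), `objective_value`, `n_restarts`, `seed`.
#' @export
select_bandwidth <- function(x, y, degree = 0, kernel = "gaussian",
                             method = c("cv.ls", "cv.aic", "plugin"),
                             bounds = c(0.05, 5), n_restarts = 5, seed = 1,
                             ridge = 1e-8) {
  method <- match.arg(method)
  degree <- normalize_degree(degree)
  x <- as.matrix(x)
  d <- ncol(x)
  stopifnot(length(bounds) == 2, all(bounds > 0), bounds[1] < bounds[2],
            n_restarts >= 1)

  if (method == "plugin") {
    if (d > 1 || degree != 1L) {
      abort_kw(
        "The direct plug-in method supports only one descriptor with the local-linear estimator; use cv.ls or cv.aic.",
        "kwlpr_error_unsupported"
      )
    }
    h <- plugin_bandwidth(x, y, bounds)
    return(structure(
      list(method = method, selected = h,
           objective_value = lscv_objective(x, y, h, degree, kernel,
                                            ridge = ridge),
           n_restarts = 0L, seed = as.integer(seed)),
      class = "kw_bwsel"
    ))
  }

  obj_raw <- switch(method,
    cv.ls = function(h) lscv_objective(x, y, h, degree, kernel, ridge = ridge),
    cv.aic = function(h) aicc_objective(x, y, h, degree, kernel, ridge = ridge)
  )
  big <- 1e10
  obj_log <- function(lh) {
    v <- obj_raw(exp(lh))
    if (!is.finite(v)) big else v
  }

  llo <- log(bounds[1]); lhi <- log(bounds[2])
  starts <- matrix(mean(c(llo, lhi)), nrow = 1, ncol = d)
  if (n_restarts > 1) {
    extra <- with_seed(as.integer(seed), {
      matrix(stats::runif((n_restarts - 1) * d, llo, lhi),
             nrow = n_restarts - 1, ncol = d)
    })
    starts <- rbind(starts, extra)
  }

  best_lh <- starts[1, ]
  best_val <- Inf
  for (k in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[k, ], obj_log, method = "L-BFGS-B",
                   lower = rep(llo, d), upper = rep(lhi, d),
                   control = list(maxit = 200)),
      error = function(e) NULL
    )
    if (!is.null(res) && is.finite(res$value) && res$value < best_val) {
      best_val <- res$value
      best_lh <- res$par
    }
  }

  edge_vals <- c(obj_log(rep(llo, d)), obj_log(rep(lhi, d)))
  if (all(is.finite(edge_vals)) && best_val >= min(edge_vals)) {
    if (min(edge_vals) < best_val) {
      rlang::warn(
        "No optimizer restart improved on the bounds-edge evaluations; returning the best point found.",
        class = "kwlpr_warning_bounds_edge"
      )
      edge <- if (edge_vals[1] <= edge_vals[2]) rep(llo, d) else rep(lhi, d)
      best_lh <- edge
      best_val <- min(edge_vals)
    }
  }

  h <- exp(best_lh)
  structure(
    list(method = method, selected = as.numeric(h),
         objective_value = obj_raw(h),
         n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
    class = "kw_bwsel"
  )
}

#' @export
print.kw_bwsel <- function(x, ...) {
  cat(sprintf("Bandwidth selection (%s): h = %s, objective = %.6g\n",
              x$method, paste(signif(x$selected, 4), collapse = ", "),
              x$objective_value))
  invisible(x)
}
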