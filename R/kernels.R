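#' Scalar kernel functions
#'
#' Evaluate a smoothing kernel at scaled distances `u`. Three kernels are
#' supported: `"gaussian"` \eqn{(2\pi)^{-1/2} e^{-u^2/2}}, `"epanechnikov"`
#' \eqn{0.75 (1 - u^2)} on \eqn{|u| \le 1}, and `"uniform"` \eqn{0.5} on
#' \eqn{|u| \le 1}. The compactly supported kernels are exactly zero outside
#' \eqn{[-1, 1]}. Normalisation constants are included, so each kernel
#' integrates to one; they cancel inside the regression estimator but make
#' printed weights comparable across implementations.
#'
#' @param u Numeric vector of scaled distances \eqn{(x_i - x_0)/h}.
#' @param kernel Kernel name: `"gaussian"`, `"epanechnikov"` or `"uniform"`.
#' @return Numeric vector of non-negative kernel values, same length as `u`.
#' @examples
#' kernel_value(0, "gaussian") # 1/sqrt(2*pi)
#' kernel_value(c(-0.5, 0.5, 1.1), "epanechnikov")
#' @export
kernel_value <- function(u, kernel = c("gaussian", "epanechnikov", "uniform")) {
  kernel <- match.arg(kernel)
  stopifnot(is.numeric(u))
  switch(kernel,
    gaussian = stats::dnorm(u),
    epanechnikov = ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0),
    uniform = ifelse(abs(u) <= 1, 0.5, 0)
  )
}

#' Multivariate product-kernel weights
#'
#' Weight of every training point relative to a query point: the product over
#' descriptors of scalar kernel values at per-descriptor scaled distances,
#' \eqn{w_i = \prod_j K\{(x_{ij} - x_{0j})/h_j\}}. This is the diagonal of the
#' weight matrix \eqn{W} in the locally weighted least-squares fit.
#'
#' @param x Numeric matrix of (scaled) descriptors, `n` rows by `d` columns.
#' @param x0 Numeric query point of length `d`, on the same scale as `x`.
#' @param bandwidth Numeric vector of `d` strictly positive bandwidths.
#' @param kernel Kernel name; see [kernel_value()].
#' @return Numeric vector of `n` non-negative weights.
#' @examples
#' x <- cbind(a = c(0, 1, 2), b = c(0, 1, 2))
#' product_weights(x, c(1, 1), bandwidth = c(1, 1), kernel = "gaussian")
#' @export
product_weights <- function(x, x0, bandwidth,
                            kernel = c("gaussian", "epanechnikov", "uniform")) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  x0 <- as.numeric(x0)
  bandwidth <- as.numeric(bandwidth)
  if (length(x0) != ncol(x) || length(bandwidth) != ncol(x)) {
    abort_kw(
      sprintf(
        "Dimension mismatch: x has %d columns, x0 has length %d, bandwidth has length %d.",
        ncol(x), length(x0), length(bandwidth)
      ),
      "kwlpr_error_dimension"
    )
  }
  check_bandwidth(bandwidth)
  w <- rep(1, nrow(x))
  for (j in seq_len(ncol(x))) {
    w <- w * kernel_value((x[, j] - x0[j]) / bandwidth[j], kernel)
  }
  w
}

check_bandwidth <- function(h) {
  if (!all(is.finite(h)) || any(h <= 0)) {
    abort_kw(
      "Bandwidths must be strictly positive and finite.",
      "kwlpr_error_bandwidth"
    )
  }
  invisible(h)
}

# m x n weight matrix: rows = query points, columns = training points
weight_matrix <- function(xq, xt, bandwidth, kernel) {
  w <- matrix(1, nrow(xq), nrow(xt))
  for (j in seq_len(ncol(xt))) {
    u <- outer(xq[, j], xt[, j], "-") / bandwidth[j]
    w <- w * kernel_value(u, kernel)
  }
  w
}
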