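# Independent brute-force oracles. These never call the package's solver
# internals: weights and normal equations are rebuilt from first principles.

oracle_kernel <- function(u, kernel) {
  switch(kernel,
    gaussian = exp(-u^2 / 2) / sqrt(2 * pi),
    epanechnikov = ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0),
    uniform = ifelse(abs(u) <= 1, 0.5, 0)
  )
}

oracle_weights <- function(x, x0, h, kernel) {
  apply(x, 1, function(row) prod(oracle_kernel((row - x0) / h, kernel)))
}

# explicit solve of (X^T W X) beta = X^T W y at one query point
oracle_local_fit <- function(x, y, x0, degree, h, kernel) {
  x <- as.matrix(x)
  w <- oracle_weights(x, x0, h, kernel)
  z <- if (degree == 0) matrix(1, nrow(x), 1) else cbind(1, sweep(x, 2, x0))
  a <- t(z) %*% diag(w, nrow(x)) %*% z
  b <- t(z) %*% diag(w, nrow(x)) %*% y
  as.numeric(solve(a, b))
}

oracle_predict <- function(x, y, xq, degree, h, kernel) {
  apply(as.matrix(xq), 1, function(q) {
    oracle_local_fit(x, y, q, degree, h, kernel)[1]
  })
}

# literal refit-per-left-out-point leave-one-out CV objective
oracle_lscv <- function(x, y, degree, h, kernel) {
  x <- as.matrix(x)
  n <- length(y)
  sq <- vapply(seq_len(n), function(i) {
    pred <- tryCatch(
      oracle_local_fit(x[-i, , drop = FALSE], y[-i], x[i, ], degree, h,
                       kernel)[1],
      error = function(e) NA_real_
    )
    if (is.na(pred)) 4 * var(y) else (y[i] - pred)^2
  }, numeric(1))
  mean(sq)
}

# drop every attribute except the data-frame essentials, for content-only
# comparisons of tables that carry metadata attributes
strip_attrs <- function(d) {
  d <- as.data.frame(d)
  attributes(d) <- attributes(d)[c("names", "class", "row.names")]
  d
}

# a small dataset wrapper for raw matrices (all rows training)
make_ds <- function(x, y, split = NULL) {
  x <- as.matrix(x)
  colnames(x) <- paste0("d", seq_len(ncol(x)))
  tab <- as.data.frame(x)
  tab$y <- y
  tab$split <- split %||% rep("train", length(y))
  suppressWarnings(
    kw_dataset(tab, response = "y",
               descriptors = colnames(x), split = "split")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
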