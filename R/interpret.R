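#' PCA biplot table for post-hoc model interpretation
#'
#' Local regression yields no single global equation, so variable importance
#' is assessed post hoc by principal component analysis of the auto-scaled
#' modeling variables. The eigen-decomposition of their correlation matrix
#' gives component scores and correlation-scaled loadings (eigenvector times
#' the square root of its eigenvalue), so each loading is the Pearson
#' correlation between the original variable and that component: sign gives
#' the direction of association, magnitude (in \eqn{[-1, 1]}) its strength.
#' By default the modeled response is included alongside the descriptors, so
#' the endpoint trend can be read off the biplot; set `include_response =
#' FALSE` for a descriptors-only analysis.
#'
#' Component signs are fixed by making each component's largest-magnitude
#' loading positive, so results are deterministic and invariant to row order.
#'
#' @param data A `kw_dataset`.
#' @param include_response Include the response column among the variables?
#' @param n_components Number of components to keep (default: all).
#' @return An object of class `kw_pca`: a list with tibbles `scores`
#'   (`compound_id`, `split`, `PC1`, ...), `loadings` (`variable`, `PC1`,
#'   ...) and `explained` (`component`, `eigenvalue`, `proportion`,
#'   `cumulative`).
#' @export
pca_biplot_table <- function(data, include_response = TRUE,
                             n_components = NULL) {
  roles <- kw_roles(data)
  vars <- c(roles$descriptors, if (include_response) roles$response)
  if (length(vars) < 2) {
    abort_kw("PCA needs at least two variables; include the response or add descriptors.",
             "kwlpr_error_validation")
  }
  m <- as.matrix(data[, vars, drop = FALSE])
  sds <- apply(m, 2, stats::sd)
  if (any(sds <= 0)) {
    abort_kw(sprintf("Constant column(s): %s.",
                     paste(vars[sds <= 0], collapse = ", ")),
             "kwlpr_error_zero_variance")
  }
  z <- scale(m)
  r <- stats::cor(m)
  eig <- eigen(r, symmetric = TRUE)
  k <- min(n_components %||% length(vars), length(vars))
  values <- pmax(eig$values[seq_len(k)], 0)
  vectors <- eig$vectors[, seq_len(k), drop = FALSE]

  loadings <- sweep(vectors, 2, sqrt(values), "*")
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      vectors[, j] <- -vectors[, j]
    }
  }
  scores <- z %*% vectors
  pc <- paste0("PC", seq_len(k))

  scores_tb <- tibble::as_tibble(stats::setNames(as.data.frame(scores), pc))
  scores_tb <- dplyr::bind_cols(
    tibble::tibble(compound_id = data$compound_id, split = data$split),
    scores_tb
  )
  loadings_tb <- dplyr::bind_cols(
    tibble::tibble(variable = vars),
    tibble::as_tibble(stats::setNames(as.data.frame(loadings), pc))
  )
  explained <- tibble::tibble(
    component = pc,
    eigenvalue = values,
    proportion = values / length(vars),
    cumulative = cumsum(values / length(vars))
  )
  structure(list(scores = scores_tb, loadings = loadings_tb,
                 explained = explained, variables = vars),
            class = "kw_pca")
}

#' Pairwise Pearson correlation
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return The Pearson correlation coefficient.
#' @export
pairwise_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    abort_kw("Need two vectors of equal length >= 3.", "kwlpr_error_dimension")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort_kw("Correlation undefined: zero variance.",
             "kwlpr_error_undefined_metric")
  }
  stats::cor(a, b)
}

#' Textual notes on variable relationships from biplot geometry
#'
#' Translates the loading geometry of the first two components into the
#' conventional biplot reading for every variable pair: an adjacent angle
#' between loading vectors implies positive correlation, a straight angle
#' negative correlation and a right angle no correlation.
#'
#' @param pca A `kw_pca` object.
#' @return A tibble with columns `var_a`, `var_b`, `angle_deg`, `cos_angle`
#'   and `note`.
#' @export
biplot_notes <- function(pca) {
  stopifnot(inherits(pca, "kw_pca"))
  l <- as.matrix(pca$loadings[, c("PC1", "PC2")])
  vars <- pca$loadings$variable
  pairs <- utils::combn(seq_along(vars), 2)
  res <- apply(pairs, 2, function(idx) {
    a <- l[idx[1], ]; b <- l[idx[2], ]
    cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    cosang <- max(-1, min(1, cosang))
    ang <- acos(cosang) * 180 / pi
    note <- if (ang < 45) {
      "adjacent angle: strong positive association"
    } else if (ang < 80) {
      "acute angle: moderate positive association"
    } else if (ang <= 100) {
      "near-right angle: little or no association"
    } else if (ang <= 135) {
      "obtuse angle: moderate negative association"
    } else {
      "near-straight angle: strong negative association"
    }
    c(vars[idx[1]], vars[idx[2]], ang, cosang, note)
  })
  tibble::tibble(
    var_a = res[1, ], var_b = res[2, ],
    angle_deg = as.numeric(res[3, ]),
    cos_angle = as.numeric(res[4, ]),
    note = res[5, ]
  )
}

#' @export
print.kw_pca <- function(x, ...) {
  cat(sprintf("PCA of %d variables: %s\n", length(x$variables),
              paste(x$variables, collapse = ", ")))
  print(x$explained)
  cat("Correlation-scaled loadings:\n")
  print(x$loadings)
  invisible(x)
}
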