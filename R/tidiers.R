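#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted model: one row per descriptor with its bandwidth
#'
#' @param x A fitted `kwlpr` model.
#' @param ... Unused.
#' @return A tibble with columns `term` and `bandwidth` (scaled scale).
#' @export
tidy.kwlpr <- function(x, ...) {
  tibble::tibble(term = names(x$bandwidth), bandwidth = unname(x$bandwidth))
}

#' Glance at a fitted model: the one-row validation panel
#'
#' @inheritParams tidy.kwlpr
#' @return The [kw_validate()] report as a plain one-row tibble.
#' @export
glance.kwlpr <- function(x, ...) {
  tibble::as_tibble(kw_validate(x))
}

#' Augment the modeling dataset with predictions and residuals
#'
#' @inheritParams tidy.kwlpr
#' @param data Data frame of compounds to predict; default the full dataset
#'   the model was built from.
#' @return `data` with columns `.fitted` and (when the response column is
#'   present) `.resid` appended.
#' @export
augment.kwlpr <- function(x, data = NULL, ...) {
  data <- tibble::as_tibble(data %||% x$dataset)
  data$.fitted <- predict(x, data)
  resp <- x$roles$response
  if (resp %in% names(data)) {
    data$.resid <- data[[resp]] - data$.fitted
  }
  data
}

#' Tidy a Y-scrambling result: one row per permutation
#'
#' @param x A `kw_scramble` object.
#' @param ... Unused.
#' @export
tidy.kw_scramble <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summarize a Y-scrambling result
#'
#' The empirical p-value is the fraction of random permutations whose
#' calibration R2 is at least the unscrambled R2.
#'
#' @inheritParams tidy.kw_scramble
#' @return One-row tibble: `n_permutations`, `n_failed`, `true_r2`,
#'   `true_q2`, `mean_permuted_r2`, `max_permuted_r2`, `p_value`, `seed`.
#' @export
glance.kw_scramble <- function(x, ...) {
  perm <- x$r2[x$permutation > 0]
  perm_ok <- perm[!is.na(perm)]
  true_r2 <- attr(x, "true_r2")
  tibble::tibble(
    n_permutations = attr(x, "n_permutations"),
    n_failed = attr(x, "n_failed"),
    true_r2 = true_r2,
    true_q2 = attr(x, "true_q2"),
    mean_permuted_r2 = mean(perm_ok),
    max_permuted_r2 = max(perm_ok),
    p_value = mean(perm_ok >= true_r2),
    seed = attr(x, "seed")
  )
}

#' Tidy a PCA summary: loadings in long form
#'
#' @param x A `kw_pca` object.
#' @param ... Unused.
#' @return A tibble with columns `variable`, `component`, `loading`.
#' @export
tidy.kw_pca <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"variable", names_to = "component",
                      values_to = "loading")
}

#' Summarize a PCA: explained variance per component
#'
#' @inheritParams tidy.kw_pca
#' @export
glance.kw_pca <- function(x, ...) {
  x$explained
}
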