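#' Critical leverage for the Williams plot
#'
#' The conventional cutoff \eqn{h^* = 3(d + 1)/n_{train}}, where `d` is the
#' number of descriptors (so `d + 1` counts the intercept of the global
#' design matrix).
#'
#' @param n_train Number of training compounds.
#' @param d Number of descriptor columns.
#' @return The critical leverage, a positive scalar.
#' @examples
#' critical_leverage(254, 2) # 9/254 = 0.035
#' @export
critical_leverage <- function(n_train, d) {
  stopifnot(n_train > 0, d >= 1)
  3 * (d + 1) / n_train
}

#' Leverages of all compounds against the training descriptor space
#'
#' Classical Williams-plot leverage: with \eqn{U} the training design matrix
#' `[1 | scaled descriptors]`, the leverage of a compound with design row
#' \eqn{u} is \eqn{h = u^T (U^T U)^{-1} u}. Validation compounds are scored
#' against the training normal matrix without refitting, so the domain of a
#' new compound can be assessed before prediction. Training leverages sum to
#' `d + 1`. Although the regression model itself is nonparametric, the
#' applicability-domain analysis follows this model-agnostic leverage
#' convention.
#'
#' @param data A `kw_dataset`.
#' @param scaler Optional `kw_scaler`; default fits one on the training split.
#' @return A tibble with columns `compound_id`, `split`, `leverage` and
#'   `x_outlier` (`leverage > h_star`, strict), with the critical leverage in
#'   attribute `"h_star"`.
#' @export
leverages <- function(data, scaler = NULL) {
  roles <- kw_roles(data)
  scaler <- scaler %||% fit_scaler(data)
  scaled <- scale_descriptors(data, scaler)
  x_all <- descriptor_matrix(scaled, roles$descriptors)
  u_all <- cbind(1, x_all)
  u_tr <- u_all[data$split == "train", , drop = FALSE]

  xtx <- crossprod(u_tr)
  inv <- tryCatch(solve(xtx), error = function(e) NULL)
  if (is.null(inv)) {
    qr_u <- qr(u_tr)
    dep <- colnames(u_tr)[-seq_len(qr_u$rank)]
    abort_kw(
      sprintf("Training design matrix is rank deficient (collinear descriptors%s).",
              if (length(dep)) paste0(": ", paste(dep, collapse = ", ")) else ""),
      "kwlpr_error_rank"
    )
  }
  h <- rowSums((u_all %*% inv) * u_all)
  h_star <- critical_leverage(nrow(u_tr), length(roles$descriptors))
  structure(
    tibble::tibble(
      compound_id = data$compound_id,
      split = data$split,
      leverage = h,
      x_outlier = h > h_star
    ),
    h_star = h_star
  )
}

#' Williams-plot table: leverage versus standardized residual
#'
#' Combines leverages with residuals standardized by the training RMSE
#' (the same scale is used for training and validation rows). A compound is
#' an X-outlier when its leverage strictly exceeds \eqn{h^* = 3(d+1)/n} --
#' structurally outside the training domain -- and a Y-outlier when its
#' standardized residual strictly exceeds 3 in magnitude -- a response
#' outlier. Points exactly on either boundary are not flagged.
#'
#' @param model A fitted `kwlpr` model.
#' @return A tibble of class `kw_ad` with columns `compound_id`, `split`,
#'   `observed`, `predicted`, `residual`, `leverage`,
#'   `standardized_residual`, `x_outlier`, `y_outlier`; attributes `h_star`,
#'   `rmse_c` and `residual_band` (3).
#' @export
williams_table <- function(model) {
  stopifnot(inherits(model, "kwlpr"))
  report <- kw_validate(model)
  preds <- attr(report, "predictions")
  rmse_c <- report$rmse_c
  # an (essentially) interpolating fit leaves no residual scale to
  # standardize against
  if (rmse_c <= 1e-10 * max(1, diff(range(preds$observed)))) {
    abort_kw("Standardized residuals are undefined: the calibration RMSE is zero.",
             "kwlpr_error_undefined_metric")
  }
  lev <- leverages(model$dataset, model$scaler)
  band <- 3
  out <- dplyr::mutate(
    dplyr::left_join(preds, lev, by = c("compound_id", "split")),
    standardized_residual = .data$residual / rmse_c,
    y_outlier = abs(.data$standardized_residual) > band
  )
  out <- out[, c("compound_id", "split", "observed", "predicted", "residual",
                 "leverage", "standardized_residual", "x_outlier", "y_outlier")]
  structure(out, h_star = attr(lev, "h_star"), rmse_c = rmse_c,
            residual_band = band,
            class = c("kw_ad", class(out)))
}

#' @export
print.kw_ad <- function(x, ...) {
  cat(sprintf(
    "Applicability domain: h* = %.4g, residual band = +/-%d, %d X-outlier(s), %d Y-outlier(s)\n",
    attr(x, "h_star"), attr(x, "residual_band"),
    sum(x$x_outlier), sum(x$y_outlier)
  ))
  NextMethod()
}
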