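#' Determination coefficient and root-mean-square error
#'
#' \eqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2} and
#' \eqn{RMSE = \sqrt{\sum(y - \hat y)^2 / n}}. The `1/n` denominator is used
#' for every RMSE variant in the package (calibration, cross-validation,
#' prediction) for consistency with common QSAR reporting.
#'
#' @param observed Numeric vector of observed responses.
#' @param predicted Numeric vector of predictions, same length.
#' @return A one-row tibble with columns `r2` and `rmse`.
#' @examples
#' r2_rmse(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' @export
r2_rmse <- function(observed, predicted) {
  check_pairs(observed, predicted)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0) {
    abort_kw("R2 is undefined: the observed values have zero variance.",
             "kwlpr_error_undefined_metric")
  }
  ss_res <- sum((observed - predicted)^2)
  tibble::tibble(r2 = 1 - ss_res / ss_tot,
                 rmse = sqrt(ss_res / length(observed)))
}

#' External predictivity coefficients Q2-F1, Q2-F2 and Q2-F3
#'
#' The three standard external validation coefficients, differing only in the
#' reference variance:
#' \deqn{Q^2_{F1} = 1 - \frac{\sum(y_v - \hat y_v)^2}{\sum(y_v - \bar y_{train})^2}, \quad
#'       Q^2_{F2} = 1 - \frac{\sum(y_v - \hat y_v)^2}{\sum(y_v - \bar y_{valid})^2}, \quad
#'       Q^2_{F3} = 1 - \frac{\sum(y_v - \hat y_v)^2 / n_v}{\sum(y_t - \bar y_{train})^2 / n_t}}
#' Q2-F1 and Q2-F2 coincide whenever the validation mean equals the training
#' mean.
#'
#' @param y_valid Observed validation responses (length >= 2).
#' @param yhat_valid Predicted validation responses.
#' @param y_train Observed training responses (length >= 2).
#' @return A one-row tibble with columns `q2_f1`, `q2_f2`, `q2_f3`.
#' @examples
#' q2_external(c(2, 4), c(2.5, 3.5), y_train = c(2, 3, 4))
#' @export
q2_external <- function(y_valid, yhat_valid, y_train) {
  check_pairs(y_valid, yhat_valid)
  if (length(y_train) < 2) {
    abort_kw("Need at least 2 training responses.", "kwlpr_error_undefined_metric")
  }
  press <- sum((y_valid - yhat_valid)^2)
  den_f1 <- sum((y_valid - mean(y_train))^2)
  den_f2 <- sum((y_valid - mean(y_valid))^2)
  den_f3 <- sum((y_train - mean(y_train))^2) / length(y_train)
  if (den_f1 <= 0 || den_f2 <= 0 || den_f3 <= 0) {
    abort_kw("External Q2 undefined: a reference variance is zero.",
             "kwlpr_error_undefined_metric")
  }
  tibble::tibble(
    q2_f1 = 1 - press / den_f1,
    q2_f2 = 1 - press / den_f2,
    q2_f3 = 1 - (press / length(y_valid)) / den_f3
  )
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between observation and prediction penalizing both location and
#' scale shifts: \eqn{CCC = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)}
#' with population (1/n) moments, Lin's original form.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return The concordance coefficient, in \eqn{[-1, 1]}.
#' @examples
#' ccc(c(1, 2, 3), c(2, 3, 4)) # 4/7: perfect correlation, shifted mean
#' @export
ccc <- function(observed, predicted) {
  check_pairs(observed, predicted)
  n <- length(observed)
  mx <- mean(observed); my <- mean(predicted)
  sx2 <- mean((observed - mx)^2)
  sy2 <- mean((predicted - my)^2)
  sxy <- mean((observed - mx) * (predicted - my))
  den <- sx2 + sy2 + (mx - my)^2
  if (den <= 0) {
    abort_kw("CCC undefined: both sequences are constant and equal.",
             "kwlpr_error_undefined_metric")
  }
  2 * sxy / den
}

#' Leave-one-out cross-validation of a fitted model
#'
#' Each training compound is predicted with itself removed, holding the
#' selected bandwidths fixed (bandwidths are not re-selected per fold:
#' re-selection would measure bandwidth stability rather than predictive
#' ability and costs n times more). Returns
#' \eqn{Q^2_{LOO} = 1 - PRESS / \sum(y - \bar y_{train})^2} and
#' \eqn{RMSE_{CV} = \sqrt{PRESS / n}}.
#'
#' @param model A fitted `kwlpr` model with at least 3 training rows.
#' @param method `"shortcut"` for the exact hat-diagonal identity, `"refit"`
#'   for literal refitting (slower; used as an independent check).
#' @return A one-row tibble with columns `q2_loo`, `rmse_cv` and
#'   `n_unpredictable` (training rows whose leave-one-out neighborhood was
#'   empty; these are excluded from both statistics and counted here rather
#'   than silently imputed).
#' @export
q2_loo <- function(model, method = c("shortcut", "refit")) {
  stopifnot(inherits(model, "kwlpr"))
  method <- match.arg(method)
  y <- model$y_train
  if (length(y) < 3) {
    abort_kw("Need at least 3 training rows for leave-one-out validation.",
             "kwlpr_error_validation")
  }
  loo <- kw_loo_predict(model$x_train, y, model$degree, model$bandwidth,
                        model$kernel, model$ridge, method)
  ok <- !is.na(loo)
  if (sum(ok) < 3) {
    abort_kw("Leave-one-out failed for nearly all rows (empty neighborhoods).",
             "kwlpr_error_empty_neighborhood")
  }
  press <- sum((y[ok] - loo[ok])^2)
  ss <- sum((y[ok] - mean(y))^2)
  tibble::tibble(
    q2_loo = 1 - press / ss,
    rmse_cv = sqrt(press / sum(ok)),
    n_unpredictable = sum(!ok)
  )
}

check_pairs <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort_kw("observed and predicted must have the same length.",
             "kwlpr_error_dimension")
  }
  if (length(observed) < 2) {
    abort_kw("Need at least 2 observation/prediction pairs.",
             "kwlpr_error_undefined_metric")
  }
  if (anyNA(observed) || anyNA(predicted)) {
    abort_kw("Missing values in observed or predicted.", "kwlpr_error_missing")
  }
  invisible(TRUE)
}
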