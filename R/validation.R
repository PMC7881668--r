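#' Full internal/external validation of a fitted model
#'
#' Assembles the standard QSAR validation panel for one fitted model:
#' calibration statistics on the training split (R2, RMSE-C), leave-one-out
#' cross-validation (Q2-LOO, RMSE-CV, bandwidths held fixed), and external
#' validation on the validation split (Q2-F1/F2/F3, Lin's CCC, RMSE-P, MAE).
#' When the dataset has no validation rows the external columns are `NA`
#' (absent, never zero). Values are kept at full precision; the print method
#' rounds to two decimals.
#'
#' @param model A fitted `kwlpr` model.
#' @return A one-row tibble of class `kw_report` with columns `n_train`,
#'   `n_valid`, `r2`, `rmse_c`, `q2_loo`, `rmse_cv`, `q2_f1`, `q2_f2`,
#'   `q2_f3`, `ccc`, `rmse_p`, `mae`. The per-compound predictions table
#'   (columns `compound_id`, `split`, `observed`, `predicted`, `residual`) is
#'   attached as attribute `"predictions"`.
#' @examples
#' ds <- generate_fixture("qsaar2d", n_train = 60, n_valid = 20, seed = 1)
#' fit <- kwlpr(ds, degree = 0, bandwidth = c(0.5, 0.5))
#' kw_validate(fit)
#' @export
kw_validate <- function(model) {
  stopifnot(inherits(model, "kwlpr"))
  ds <- model$dataset
  resp <- model$roles$response
  pred_all <- predict(model, ds)
  preds <- tibble::tibble(
    compound_id = ds$compound_id,
    split = ds$split,
    observed = ds[[resp]],
    predicted = pred_all,
    residual = ds[[resp]] - pred_all
  )

  tr <- preds[preds$split == "train", ]
  va <- preds[preds$split == "validation", ]

  cal <- r2_rmse(tr$observed, tr$predicted)
  loo <- q2_loo(model)

  if (nrow(va) >= 2) {
    ext <- q2_external(va$observed, va$predicted, tr$observed)
    ext_ccc <- ccc(va$observed, va$predicted)
    rmse_p <- sqrt(mean((va$observed - va$predicted)^2))
    mae <- mean(abs(va$observed - va$predicted))
  } else {
    ext <- tibble::tibble(q2_f1 = NA_real_, q2_f2 = NA_real_, q2_f3 = NA_real_)
    ext_ccc <- NA_real_
    rmse_p <- NA_real_
    mae <- NA_real_
  }

  out <- tibble::tibble(
    n_train = nrow(tr), n_valid = nrow(va),
    r2 = cal$r2, rmse_c = cal$rmse,
    q2_loo = loo$q2_loo, rmse_cv = loo$rmse_cv,
    q2_f1 = ext$q2_f1, q2_f2 = ext$q2_f2, q2_f3 = ext$q2_f3,
    ccc = ext_ccc, rmse_p = rmse_p, mae = mae
  )
  structure(out, predictions = preds,
            class = c("kw_report", class(out)))
}

#' Recompute a validation report from a saved predictions table
#'
#' Audit path: re-derives every metric of [kw_validate()] from a predictions
#' table (as attached to a report or written to CSV by the grid runner), so
#' any summary row can be checked against its saved artifacts.
#'
#' @param predictions A data frame with columns `compound_id`, `split`,
#'   `observed`, `predicted`.
#' @param loo A data frame with columns `compound_id`, `loo_predicted` for
#'   the training rows, or `NULL` to leave the cross-validated columns `NA`.
#' @return A one-row tibble with the same columns as [kw_validate()].
#' @export
report_from_predictions <- function(predictions, loo = NULL) {
  tr <- predictions[predictions$split == "train", ]
  va <- predictions[predictions$split == "validation", ]
  cal <- r2_rmse(tr$observed, tr$predicted)

  if (!is.null(loo)) {
    m <- merge(tr, loo, by = "compound_id")
    press <- sum((m$observed - m$loo_predicted)^2)
    ss <- sum((m$observed - mean(tr$observed))^2)
    q2l <- 1 - press / ss
    rmse_cv <- sqrt(press / nrow(m))
  } else {
    q2l <- NA_real_; rmse_cv <- NA_real_
  }

  if (nrow(va) >= 2) {
    ext <- q2_external(va$observed, va$predicted, tr$observed)
    ext_ccc <- ccc(va$observed, va$predicted)
    rmse_p <- sqrt(mean((va$observed - va$predicted)^2))
    mae <- mean(abs(va$observed - va$predicted))
  } else {
    ext <- tibble::tibble(q2_f1 = NA_real_, q2_f2 = NA_real_, q2_f3 = NA_real_)
    ext_ccc <- NA_real_; rmse_p <- NA_real_; mae <- NA_real_
  }

  tibble::tibble(
    n_train = nrow(tr), n_valid = nrow(va),
    r2 = cal$r2, rmse_c = cal$rmse, q2_loo = q2l, rmse_cv = rmse_cv,
    q2_f1 = ext$q2_f1, q2_f2 = ext$q2_f2, q2_f3 = ext$q2_f3,
    ccc = ext_ccc, rmse_p = rmse_p, mae = mae
  )
}

#' @export
print.kw_report <- function(x, ...) {
  cat("Validation report (values rounded to 2 decimals)\n")
  y <- tibble::as_tibble(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, 2)
  print(y)
  invisible(x)
}

#' Y-scrambling (response-randomization) robustness test
#'
#' Refits the model `n_permutations` times after randomly permuting the
#' training responses (descriptors untouched, validation rows untouched),
#' holding degree, kernel and the originally selected bandwidths fixed, and
#' records the calibration R2 and Q2-LOO of each scrambled model. A genuine
#' structure-activity relationship collapses under scrambling, so the true R2
#' should sit far above the permuted distribution; the empirical p-value is
#' the fraction of permuted R2 values at or above the true R2.
#'
#' Permutation k draws its own RNG stream from `seed + k` (a counter scheme),
#' so results do not depend on execution order. The identity permutation is
#' included as permutation 0 and must reproduce the unscrambled statistics
#' exactly; it is excluded from the permuted vectors.
#'
#' @param model A fitted `kwlpr` model.
#' @param n_permutations Number of random permutations (the conventional
#'   choice in QSAR reporting is 500).
#' @param seed Integer master seed.
#' @return An object of class `kw_scramble`: a tibble with columns
#'   `permutation` (0 = identity), `r2` and `q2_loo`, with attributes
#'   `true_r2`, `true_q2`, `n_permutations`, `seed` and `n_failed` (fit
#'   failures, recorded and skipped).
#' @export
y_scramble <- function(model, n_permutations = 500, seed = 1) {
  stopifnot(inherits(model, "kwlpr"), n_permutations >= 1)
  x <- model$x_train
  y <- model$y_train
  n <- length(y)

  one_fit <- function(y_perm) {
    fit <- kw_predict_scaled(x, x, y_perm, model$degree, model$bandwidth,
                             model$kernel, model$ridge, hat = TRUE)
    if (anyNA(fit$pred)) return(c(NA_real_, NA_real_))
    r2 <- 1 - sum((y_perm - fit$pred)^2) / sum((y_perm - mean(y_perm))^2)
    denom <- 1 - fit$hat
    loo <- (fit$pred - fit$hat * y_perm) / denom
    ok <- is.finite(loo) & denom > 1e-12
    q2 <- if (sum(ok) >= 3) {
      1 - sum((y_perm[ok] - loo[ok])^2) / sum((y_perm[ok] - mean(y_perm))^2)
    } else NA_real_
    c(r2, q2)
  }

  rows <- vector("list", n_permutations + 1)
  rows[[1]] <- c(0, one_fit(y))
  n_failed <- 0L
  for (k in seq_len(n_permutations)) {
    y_perm <- with_seed(as.integer(seed) + k, y[sample.int(n)])
    st <- tryCatch(one_fit(y_perm), error = function(e) c(NA_real_, NA_real_))
    if (anyNA(st[1])) n_failed <- n_failed + 1L
    rows[[k + 1]] <- c(k, st)
  }
  m <- do.call(rbind, rows)
  out <- tibble::tibble(permutation = as.integer(m[, 1]),
                        r2 = m[, 2], q2_loo = m[, 3])
  structure(out,
            true_r2 = out$r2[1], true_q2 = out$q2_loo[1],
            n_permutations = as.integer(n_permutations),
            seed = as.integer(seed), n_failed = n_failed,
            class = c("kw_scramble", class(out)))
}

#' @export
print.kw_scramble <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Y-scrambling: %d permutations, true R2 = %.3f, permuted R2 mean = %.3f (max %.3f), empirical p = %.4g\n",
    g$n_permutations, g$true_r2, g$mean_permuted_r2, g$max_permuted_r2,
    g$p_value
  ))
  invisible(x)
}
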