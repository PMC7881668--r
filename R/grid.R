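#' Run the full modeling grid on one dataset
#'
#' End-to-end runner: auto-scales the data, then for every requested
#' combination of estimator (`lc`, `ll`), bandwidth selection method
#' (`cv.ls`, `cv.aic`, `plugin`) and kernel (`gaussian`, `epanechnikov`,
#' `uniform`) selects bandwidths, fits the model and computes the full
#' validation panel. One summary row is produced per combination; a
#' combination that fails (e.g. `plugin` with several descriptors) carries an
#' error status rather than being silently dropped. With `fix_bandwidth` the
#' selection step is skipped and a single fixed-bandwidth model per
#' estimator/kernel pair is evaluated -- the replication mode for checking a
#' published model whose bandwidths are known.
#'
#' When `outdir` is given, the runner writes `summary.csv`, a resolved
#' `config.txt` and a `run_log.txt` (input hash, seed, grid, package
#' version) in `outdir`, plus one subdirectory per combination under
#' `combos/` containing `predictions.csv` (with leverage and standardized
#' residual columns), `loo_predictions.csv`, `report.csv` and `ad.csv`, so
#' that every summary row can be re-derived from its artifacts. Given the
#' same seed and input the summary is byte-identical across runs (the
#' `runtime_s` column aside).
#'
#' @param data A `kw_dataset` or a data frame plus role arguments.
#' @inheritParams kwlpr
#' @param estimators Character subset of `c("lc", "ll")`.
#' @param bw_methods Character subset of `c("cv.ls", "cv.aic", "plugin")`;
#'   ignored when `fix_bandwidth` is given.
#' @param kernels Character subset of
#'   `c("gaussian", "epanechnikov", "uniform")`.
#' @param fix_bandwidth Optional numeric vector of per-descriptor bandwidths
#'   (scaled scale) replacing automatic selection.
#' @param n_scramble If positive, run a Y-scrambling test with this many
#'   permutations for each successful combination and record its empirical
#'   p-value.
#' @param outdir Output directory, or `NULL` for no files.
#' @return A tibble of class `kw_grid`, one row per combination: the grid
#'   coordinates, selected bandwidths (comma-separated, full precision), the
#'   validation panel, optional scrambling p-value, `status`
#'   (`"ok"`/`"error"`), `error` message and `runtime_s`.
#' @export
run_grid <- function(data, response = NULL, descriptors = NULL, id = NULL,
                     split = NULL,
                     estimators = c("lc", "ll"),
                     bw_methods = c("cv.ls", "cv.aic"),
                     kernels = c("gaussian", "epanechnikov", "uniform"),
                     fix_bandwidth = NULL, bw_bounds = c(0.05, 5),
                     n_restarts = 5, n_scramble = 0, seed = 1,
                     outdir = NULL) {
  estimators <- match.arg(estimators, c("lc", "ll"), several.ok = TRUE)
  kernels <- match.arg(kernels,
                       c("gaussian", "epanechnikov", "uniform"),
                       several.ok = TRUE)
  if (!inherits(data, "kw_dataset")) {
    data <- kw_dataset(data, response = response, descriptors = descriptors,
                       id = id, split = split)
  }
  if (length(fix_bandwidth) == 0) fix_bandwidth <- NULL
  if (is.null(fix_bandwidth)) {
    bw_methods <- match.arg(bw_methods, c("cv.ls", "cv.aic", "plugin"),
                            several.ok = TRUE)
  } else {
    bw_methods <- "fixed"
  }

  grid <- expand.grid(estimator = estimators, bw_method = bw_methods,
                      kernel = kernels, stringsAsFactors = FALSE)
  grid <- grid[order(grid$estimator, grid$bw_method, grid$kernel), ]

  if (!is.null(outdir)) {
    dir.create(file.path(outdir, "combos"), recursive = TRUE,
               showWarnings = FALSE)
  }

  rows <- vector("list", nrow(grid))
  artifacts <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    combo_seed <- as.integer(seed) + i
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      fit <- kwlpr(
        data, degree = g$estimator, kernel = g$kernel,
        bandwidth = fix_bandwidth,
        bw_method = if (g$bw_method == "fixed") "cv.ls" else g$bw_method,
        bw_bounds = bw_bounds, n_restarts = n_restarts, seed = combo_seed
      )
      report <- kw_validate(fit)
      ad <- williams_table(fit)
      loo <- kw_loo_predict(fit$x_train, fit$y_train, fit$degree,
                            fit$bandwidth, fit$kernel, fit$ridge)
      scramble_p <- NA_real_
      if (n_scramble > 0) {
        sc <- y_scramble(fit, n_permutations = n_scramble, seed = combo_seed)
        scramble_p <- glance(sc)$p_value
      }
      list(fit = fit, report = report, ad = ad,
           loo = tibble::tibble(compound_id = fit$train_ids,
                                loo_predicted = loo),
           scramble_p = scramble_p, error = NA_character_)
    }, error = function(e) list(fit = NULL, report = NULL, ad = NULL,
                                loo = NULL, scramble_p = NA_real_,
                                error = conditionMessage(e)))
    runtime <- proc.time()[["elapsed"]] - t0

    if (is.null(res$report)) {
      row <- tibble::tibble(
        estimator = g$estimator, bw_method = g$bw_method, kernel = g$kernel,
        bandwidth = NA_character_, n_train = NA_integer_,
        n_valid = NA_integer_, r2 = NA_real_, rmse_c = NA_real_,
        q2_loo = NA_real_, rmse_cv = NA_real_, q2_f1 = NA_real_,
        q2_f2 = NA_real_, q2_f3 = NA_real_, ccc = NA_real_,
        rmse_p = NA_real_, mae = NA_real_, scramble_p = NA_real_,
        status = "error", error = res$error, runtime_s = runtime
      )
    } else {
      row <- dplyr::bind_cols(
        tibble::tibble(
          estimator = g$estimator, bw_method = g$bw_method, kernel = g$kernel,
          bandwidth = paste(format(res$fit$bandwidth, digits = 15,
                                   scientific = FALSE, trim = TRUE),
                            collapse = ",")
        ),
        tibble::as_tibble(res$report),
        tibble::tibble(scramble_p = res$scramble_p, status = "ok",
                       error = NA_character_, runtime_s = runtime)
      )
    }
    rows[[i]] <- row
    artifacts[[i]] <- res
  }

  summary <- dplyr::bind_rows(rows)
  class(summary) <- c("kw_grid", class(summary))

  if (!is.null(outdir)) {
    write_grid_outputs(summary, artifacts, grid, data, seed, outdir)
  }
  summary
}

combo_label <- function(estimator, bw_method, kernel) {
  paste(estimator, bw_method, kernel, sep = "_")
}

write_grid_outputs <- function(summary, artifacts, grid, data, seed, outdir) {
  out <- summary
  out$runtime_s <- NULL # kept in the returned object; excluded from the file
  readr::write_csv(out, file.path(outdir, "summary.csv"), progress = FALSE)

  tmp <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(data), tmp, progress = FALSE)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)

  writeLines(c(
    sprintf("input_md5=%s", hash),
    sprintf("seed=%d", as.integer(seed)),
    sprintf("n_rows=%d", nrow(data)),
    sprintf("grid=%s", paste(combo_label(grid$estimator, grid$bw_method,
                                         grid$kernel), collapse = ";")),
    sprintf("kwlpr_version=%s",
            as.character(utils::packageVersion("kwlpr"))),
    sprintf("r_version=%s", R.version.string)
  ), file.path(outdir, "run_log.txt"))

  roles <- kw_roles(data)
  writeLines(c(
    sprintf("response=%s", roles$response),
    sprintf("descriptors=%s", paste(roles$descriptors, collapse = ",")),
    sprintf("seed=%d", as.integer(seed))
  ), file.path(outdir, "config.txt"))

  for (i in seq_len(nrow(grid))) {
    res <- artifacts[[i]]
    if (is.null(res$report)) next
    g <- grid[i, ]
    dir <- file.path(outdir, "combos",
                     combo_label(g$estimator, g$bw_method, g$kernel))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ad <- tibble::as_tibble(res$ad)
    preds <- ad # predictions table incl. leverage + standardized residual
    readr::write_csv(preds, file.path(dir, "predictions.csv"),
                     progress = FALSE)
    readr::write_csv(res$loo, file.path(dir, "loo_predictions.csv"),
                     progress = FALSE)
    readr::write_csv(tibble::as_tibble(res$report),
                     file.path(dir, "report.csv"), progress = FALSE)
    readr::write_csv(ad, file.path(dir, "ad.csv"), progress = FALSE)
  }
  invisible(summary)
}

#' @export
print.kw_grid <- function(x, ...) {
  cat(sprintf("Modeling grid: %d combination(s), %d ok, %d failed\n",
              nrow(x), sum(x$status == "ok"), sum(x$status != "ok")))
  y <- tibble::as_tibble(x)
  num <- vapply(y, is.double, logical(1))
  y[num] <- lapply(y[num], round, 3)
  print(y[, c("estimator", "bw_method", "kernel", "bandwidth", "r2",
              "rmse_c", "q2_loo", "q2_f1", "q2_f2", "q2_f3", "ccc",
              "rmse_p", "status")])
  invisible(x)
}
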