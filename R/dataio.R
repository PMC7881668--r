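#' Build a modeling dataset from a compound table
#'
#' Validates a data frame of compounds against the column roles used
#' throughout the package: a compound identifier, a train/validation split
#' flag, one numeric response (the modeled endpoint, e.g. pLC50) and one or
#' more numeric descriptor columns. Rows with missing response or descriptor
#' values are rejected, not dropped, so the reported training/validation
#' counts always match the input.
#'
#' Split labels are matched case-insensitively: `train`, `training` and `t`
#' map to the training set; `valid`, `validation`, `test` and `v` map to the
#' validation set.
#'
#' @param data A data frame with one row per compound.
#' @param response Name of the response column.
#' @param descriptors Character vector of descriptor column names. Default
#'   `NULL` uses every numeric column other than the response.
#' @param id Name of the compound-identifier column, or `NULL` to generate
#'   sequential labels.
#' @param split Name of the split column, or `NULL` to place every row in the
#'   training set (external validation is then unavailable).
#' @return A tibble of class `kw_dataset` with standardized columns
#'   `compound_id`, `split`, the response and the descriptors. Column roles
#'   are recorded in the `"kw_roles"` attribute.
#' @examples
#' d <- data.frame(
#'   id = paste0("c", 1:6), set = c(rep("train", 4), "valid", "valid"),
#'   y = rnorm(6), x1 = rnorm(6), x2 = rnorm(6)
#' )
#' ds <- kw_dataset(d, response = "y", descriptors = c("x1", "x2"),
#'                  id = "id", split = "set")
#' kw_roles(ds)
#' @export
kw_dataset <- function(data, response, descriptors = NULL, id = NULL,
                       split = NULL) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)

  for (col in c(response, descriptors, id, split)) {
    if (!col %in% names(data)) {
      abort_kw(sprintf("Column '%s' not found in the input table.", col),
               "kwlpr_error_schema")
    }
  }

  compound_id <- if (is.null(id)) {
    sprintf("compound_%03d", seq_len(nrow(data)))
  } else {
    as.character(data[[id]])
  }

  split_lab <- if (is.null(split)) rep("train", nrow(data)) else
    normalize_split(data[[split]])

  if (is.null(descriptors)) {
    cand <- setdiff(names(data), c(response, id, split))
    descriptors <- cand[vapply(data[cand], is.numeric, logical(1))]
  }
  if (length(descriptors) < 1) {
    abort_kw("At least one descriptor column is required.",
             "kwlpr_error_schema")
  }

  out <- tibble::tibble(compound_id = compound_id, split = split_lab)
  out[[response]] <- check_numeric_column(data[[response]], response)
  for (d in descriptors) {
    out[[d]] <- check_numeric_column(data[[d]], d)
  }

  n_train <- sum(out$split == "train")
  if (n_train == 0) {
    abort_kw("The training split is empty.", "kwlpr_error_validation")
  }
  if (n_train < length(descriptors) + 2) {
    abort_kw(
      sprintf(
        "Need at least %d training rows for %d descriptor(s); got %d.",
        length(descriptors) + 2, length(descriptors), n_train
      ),
      "kwlpr_error_validation"
    )
  }
  if (!any(out$split == "validation")) {
    rlang::warn(
      "No validation rows: external validation metrics will be unavailable.",
      class = "kwlpr_warning_no_validation"
    )
  }

  structure(
    out,
    kw_roles = list(response = response, descriptors = descriptors),
    class = c("kw_dataset", class(out))
  )
}

#' @rdname kw_dataset
#' @param x A `kw_dataset`.
#' @export
kw_roles <- function(x) {
  roles <- attr(x, "kw_roles")
  if (is.null(roles)) {
    abort_kw("Not a kw_dataset: column roles are missing.",
             "kwlpr_error_schema")
  }
  roles
}

normalize_split <- function(x) {
  lab <- tolower(trimws(as.character(x)))
  train <- lab %in% c("train", "training", "t")
  valid <- lab %in% c("valid", "validation", "test", "v")
  if (any(!train & !valid)) {
    bad <- unique(lab[!train & !valid])
    abort_kw(
      sprintf("Unrecognized split label(s): %s.", paste(bad, collapse = ", ")),
      "kwlpr_error_schema"
    )
  }
  ifelse(train, "train", "validation")
}

check_numeric_column <- function(x, name) {
  if (!is.numeric(x)) {
    conv <- suppressWarnings(as.numeric(as.character(x)))
    bad <- which(is.na(conv) & !is.na(x))
    if (length(bad)) {
      abort_kw(
        sprintf("Column '%s' has a non-numeric value at row %d ('%s').",
                name, bad[1], as.character(x[bad[1]])),
        "kwlpr_error_parse"
      )
    }
    x <- conv
  }
  if (anyNA(x)) {
    abort_kw(
      sprintf("Column '%s' has a missing value at row %d; rows with missing values are rejected, not imputed.",
              name, which(is.na(x))[1]),
      "kwlpr_error_missing"
    )
  }
  as.double(x)
}

#' Read a modeling dataset from a CSV file
#'
#' Reads a comma-separated compound table (header row required, `.` decimal
#' mark, UTF-8) and validates it with [kw_dataset()]. Column roles are given
#' explicitly by name, never positionally.
#'
#' @param path Path to the CSV file.
#' @inheritParams kw_dataset
#' @return A `kw_dataset` tibble; row order is preserved.
#' @export
read_dataset <- function(path, response, descriptors = NULL, id = NULL,
                         split = NULL) {
  if (!file.exists(path)) {
    abort_kw(sprintf("Input file '%s' does not exist.", path),
             "kwlpr_error_io")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  kw_dataset(raw, response = response, descriptors = descriptors, id = id,
             split = split)
}

#' Write a dataset (or any prediction table) to CSV
#'
#' @param data A data frame, typically a `kw_dataset` or a predictions table.
#' @param path Output file path.
#' @return `data`, invisibly.
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(data)
}

#' Fit an auto-scaling (standardization) model on the training split
#'
#' Auto-scaling centers every descriptor to zero mean and unit standard
#' deviation so that descriptors spanning different ranges receive equal
#' attention during local weighting. Parameters are estimated from the
#' training rows only and then applied to all rows, so validation compounds
#' never leak into the scaling (their scaled columns need not have mean 0).
#' The sample (n-1) standard deviation is used.
#'
#' @param data A `kw_dataset`.
#' @return An object of class `kw_scaler`: per-descriptor means and standard
#'   deviations.
#' @seealso [scale_descriptors()], [unscale_descriptors()]
#' @export
fit_scaler <- function(data) {
  roles <- kw_roles(data)
  xt <- descriptor_matrix(data[data$split == "train", ], roles$descriptors)
  if (nrow(xt) < 2) {
    abort_kw("Need at least 2 training rows to fit the scaler.",
             "kwlpr_error_validation")
  }
  mu <- colMeans(xt)
  sd <- apply(xt, 2, stats::sd)
  zero <- sd <= 0 | !is.finite(sd)
  if (any(zero)) {
    abort_kw(
      sprintf("Descriptor column(s) with zero variance in the training split: %s.",
              paste(roles$descriptors[zero], collapse = ", ")),
      "kwlpr_error_zero_variance"
    )
  }
  structure(
    list(mean = mu, sd = sd, descriptors = roles$descriptors),
    class = "kw_scaler"
  )
}

#' Apply or invert an auto-scaling model
#'
#' @param data A data frame containing the scaler's descriptor columns.
#' @param scaler A `kw_scaler` from [fit_scaler()].
#' @return `data` with descriptor columns standardized (or restored).
#' @export
scale_descriptors <- function(data, scaler) {
  stopifnot(inherits(scaler, "kw_scaler"))
  for (d in scaler$descriptors) {
    data[[d]] <- (data[[d]] - scaler$mean[[d]]) / scaler$sd[[d]]
  }
  data
}

#' @rdname scale_descriptors
#' @export
unscale_descriptors <- function(data, scaler) {
  stopifnot(inherits(scaler, "kw_scaler"))
  for (d in scaler$descriptors) {
    data[[d]] <- data[[d]] * scaler$sd[[d]] + scaler$mean[[d]]
  }
  data
}

#' @export
print.kw_scaler <- function(x, ...) {
  cat("Auto-scaling model (training-split statistics)\n")
  print(tibble::tibble(descriptor = x$descriptors,
                       mean = unname(x$mean), sd = unname(x$sd)))
  invisible(x)
}
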