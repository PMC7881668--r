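make_csv <- function(tab) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(tab, path)
  path
}

test_that("a compound CSV parses into a validated dataset", {
  tab <- tibble::tibble(
    id = paste0("c", 1:6),
    set = c("train", "train", "train", "train", "valid", "valid"),
    pLC50 = c(1.2, 2.3, 3.1, 0.8, 1.9, 2.2),
    LogP = c(0.5, 1.5, 2.5, 0.2, 1.1, 2.0),
    pEC50 = c(2.1, 3.2, 4.0, 1.8, 2.9, 3.5)
  )
  ds <- read_dataset(make_csv(tab), response = "pLC50",
                     descriptors = c("LogP", "pEC50"), id = "id",
                     split = "set")
  expect_s3_class(ds, "kw_dataset")
  expect_equal(nrow(ds), 6)
  expect_equal(kw_roles(ds)$descriptors, c("LogP", "pEC50"))
  expect_equal(sum(ds$split == "train"), 4)
  expect_equal(sum(ds$split == "validation"), 2)
  expect_equal(ds$compound_id, tab$id) # row order preserved

  # split labels are normalized case-insensitively
  tab2 <- tab
  tab2$set <- c("Training", "T", "TRAIN", "train", "Test", "V")
  ds2 <- kw_dataset(tab2, response = "pLC50", id = "id", split = "set")
  expect_equal(ds2$split, ds$split)
})

test_that("schema and content errors are specific", {
  tab <- tibble::tibble(id = paste0("c", 1:5),
                        set = c(rep("train", 4), "valid"),
                        y = c(1, 2, 3, 4, 5), x = c(1, 2, 3, 4, 5))
  expect_error(kw_dataset(tab, response = "missing", id = "id", split = "set"),
               class = "kwlpr_error_schema")
  expect_error(read_dataset("no_such_file.csv", response = "y"),
               class = "kwlpr_error_io")

  bad <- tab; bad$x <- as.character(bad$x); bad$x[3] <- "oops"
  err <- expect_error(
    kw_dataset(bad, response = "y", descriptors = "x", id = "id",
               split = "set"),
    class = "kwlpr_error_parse"
  )
  expect_match(conditionMessage(err), "row 3")
  expect_match(conditionMessage(err), "'x'")

  miss <- tab; miss$y[2] <- NA
  expect_error(kw_dataset(miss, response = "y", id = "id", split = "set"),
               class = "kwlpr_error_missing")

  tiny <- tab[c(1, 2, 5), ] # 2 train rows < d + 2
  expect_error(kw_dataset(tiny, response = "y", descriptors = "x",
                          id = "id", split = "set"),
               class = "kwlpr_error_validation")

  none <- tab; none$set <- "valid"
  expect_error(kw_dataset(none, response = "y", id = "id", split = "set"),
               class = "kwlpr_error_validation")
})

test_that("a train-only table is accepted with a warning", {
  tab <- tibble::tibble(y = rnorm(6), x = rnorm(6),
                        set = rep("train", 6))
  expect_warning(
    ds <- kw_dataset(tab, response = "y", descriptors = "x", split = "set"),
    class = "kwlpr_warning_no_validation"
  )
  expect_equal(sum(ds$split == "validation"), 0)
})

test_that("write/read round-trips a dataset", {
  ds <- generate_fixture("qsaar2d", n_train = 20, n_valid = 6, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path, response = "pLC50",
                       descriptors = c("LogP", "pEC50"),
                       id = "compound_id", split = "split")
  expect_equal(strip_attrs(back), strip_attrs(ds), tolerance = 1e-12)
})

test_that("auto-scaling is fitted on training rows only, sample sd", {
  ds1 <- make_ds(c(1, 2, 3), y = c(1, 2, 3))
  sc1 <- fit_scaler(ds1)
  expect_equal(unname(sc1$mean[1]), 2)
  expect_equal(unname(sc1$sd[1]), 1) # sample (n-1) denominator

  # scaled training block has column means 0, sds 1
  ds <- make_ds(cbind(c(1, 2, 3, 7), c(5, 6, 9, 2)), y = c(1, 2, 3, 4))
  sc <- fit_scaler(ds)
  scaled <- scale_descriptors(ds, sc)
  xs <- as.matrix(scaled[, c("d1", "d2")])
  expect_equal(colMeans(xs), c(d1 = 0, d2 = 0), tolerance = 1e-12)
  expect_equal(apply(xs, 2, sd), c(d1 = 1, d2 = 1), tolerance = 1e-12)

  # round trip
  back <- unscale_descriptors(scaled, sc)
  expect_equal(back$d1, ds$d1, tolerance = 1e-12)

  # constant column rejected, named
  const <- make_ds(cbind(c(5, 5, 5, 5), c(1, 2, 3, 4)), y = c(1, 2, 3, 4))
  err <- expect_error(fit_scaler(const), class = "kwlpr_error_zero_variance")
  expect_match(conditionMessage(err), "d1")
})

test_that("validation rows never leak into the scaler", {
  ds <- generate_fixture("qsaar2d", n_train = 30, n_valid = 10, seed = 5)
  sc <- fit_scaler(ds)
  perturbed <- ds
  idx <- perturbed$split == "validation"
  perturbed$LogP[idx] <- perturbed$LogP[idx] + 100
  attr(perturbed, "kw_roles") <- kw_roles(ds)
  sc2 <- fit_scaler(perturbed)
  expect_identical(sc$mean, sc2$mean)
  expect_identical(sc$sd, sc2$sd)
})
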