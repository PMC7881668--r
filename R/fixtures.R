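# bumped whenever any generator changes; tests reference it so frozen
# expectations are never silently compared against regenerated data
kw_fixture_version <- 1L

#' Seeded synthetic datasets for testing and demonstration
#'
#' Four generators covering the situations the estimator must handle:
#'
#' * `sine1d` -- one descriptor `x` uniform on \eqn{[0, 2\pi]}, response
#'   `y = sin(x)` plus Gaussian noise. Default noise standard deviation is
#'   `sqrt(0.5)/3`, i.e. a signal-to-noise ratio of 3:1 (the sine has
#'   standard deviation `sqrt(0.5)` under the uniform design).
#' * `linear1d` -- exact affine truth `y = 2x + 1`, noise-free by default;
#'   exercises polynomial reproduction by the local-linear estimator.
#' * `qsaar2d` -- a correlated-descriptor interspecies-extrapolation table
#'   shaped like a pesticide QSAAR study: a lipophilicity-like descriptor
#'   `LogP` and a lower-species potency `pEC50` with correlation 0.5, and a
#'   response `pLC50` that is a smooth monotone function of both plus noise
#'   (default sd 0.6). Defaults `n_train = 254`, `n_valid = 64`.
#' * `noise_only` -- two standard-normal descriptors and a response
#'   independent of them; the null fixture for Y-scrambling behavior.
#'
#' The ground-truth regression function is attached as attribute `"truth"`
#' (a function of a descriptor data frame), enabling recovery tests against
#' the noise-free signal. Identical `generator`, sizes and `seed` give an
#' identical table.
#'
#' @param generator One of `"sine1d"`, `"linear1d"`, `"qsaar2d"`,
#'   `"noise_only"`.
#' @param n_train,n_valid Split sizes; defaults depend on the generator.
#' @param noise_sd Gaussian noise standard deviation; default depends on the
#'   generator (see above).
#' @param descriptor_correlation Correlation between the two `qsaar2d`
#'   descriptors, in (-1, 1).
#' @param seed Integer seed.
#' @return A `kw_dataset` with attributes `truth` and `fixture_version`.
#' @examples
#' ds <- generate_fixture("sine1d", n_train = 40, n_valid = 10, seed = 7)
#' truth <- attr(ds, "truth")
#' head(truth(ds))
#' @export
generate_fixture <- function(generator = c("sine1d", "linear1d", "qsaar2d",
                                           "noise_only"),
                             n_train = NULL, n_valid = NULL, noise_sd = NULL,
                             descriptor_correlation = 0.5, seed = 1) {
  generator <- match.arg(generator)
  defaults <- switch(generator,
    sine1d = list(n_train = 60, n_valid = 20, noise_sd = sqrt(0.5) / 3),
    linear1d = list(n_train = 40, n_valid = 10, noise_sd = 0),
    qsaar2d = list(n_train = 254, n_valid = 64, noise_sd = 0.6),
    noise_only = list(n_train = 60, n_valid = 20, noise_sd = 1)
  )
  n_train <- n_train %||% defaults$n_train
  n_valid <- n_valid %||% defaults$n_valid
  noise_sd <- noise_sd %||% defaults$noise_sd
  stopifnot(n_train >= 3, n_valid >= 0, noise_sd >= 0,
            abs(descriptor_correlation) < 1)
  n <- n_train + n_valid

  made <- with_seed(as.integer(seed), {
    switch(generator,
      sine1d = {
        x <- stats::runif(n, 0, 2 * pi)
        truth <- function(d) sin(d$x)
        list(tab = tibble::tibble(x = x,
                                  y = sin(x) + stats::rnorm(n, 0, noise_sd)),
             truth = truth, response = "y", descriptors = "x")
      },
      linear1d = {
        x <- stats::runif(n, -2, 2)
        truth <- function(d) 2 * d$x + 1
        list(tab = tibble::tibble(x = x,
                                  y = 2 * x + 1 + stats::rnorm(n, 0, noise_sd)),
             truth = truth, response = "y", descriptors = "x")
      },
      qsaar2d = {
        rho <- descriptor_correlation
        z1 <- stats::rnorm(n)
        z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
        logp <- 3 + 1.5 * z1
        pec50 <- 4 + 1.2 * z2
        truth <- function(d) {
          0.27 + 0.17 * d$LogP + 0.67 * d$pEC50 +
            0.8 * tanh(1.5 * (d$LogP - 3))
        }
        tab <- tibble::tibble(LogP = logp, pEC50 = pec50)
        tab$pLC50 <- truth(tab) + stats::rnorm(n, 0, noise_sd)
        list(tab = tab, truth = truth, response = "pLC50",
             descriptors = c("LogP", "pEC50"))
      },
      noise_only = {
        tab <- tibble::tibble(x1 = stats::rnorm(n), x2 = stats::rnorm(n),
                              y = stats::rnorm(n, 0, noise_sd))
        list(tab = tab, truth = function(d) rep(0, nrow(d)),
             response = "y", descriptors = c("x1", "x2"))
      }
    )
  })

  tab <- made$tab
  tab$compound_id <- sprintf("%s_%04d", generator, seq_len(n))
  tab$split <- c(rep("train", n_train), rep("validation", n_valid))
  ds <- suppressWarnings(kw_dataset(
    tab, response = made$response, descriptors = made$descriptors,
    id = "compound_id", split = "split"
  ))
  attr(ds, "truth") <- made$truth
  attr(ds, "fixture_version") <- kw_fixture_version
  ds
}
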