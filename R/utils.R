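# internal helpers shared across modules

# Run `code` with a temporary RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards so package functions never disturb
# the user's random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_kw <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "kwlpr_error"), ...)
}

# descriptor columns of a dataset as a plain numeric matrix
descriptor_matrix <- function(data, descriptors) {
  m <- as.matrix(data[, descriptors, drop = FALSE])
  storage.mode(m) <- "double"
  m
}
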