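#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn %||% .data
#' @importFrom stats qnorm plogis qlogis rnorm runif rlnorm sd cor median optim
#' @useDynLib probegng, .registration = TRUE
NULL

# Fold any number of small integers into one valid 32-bit seed.
# Deterministic, order-sensitive; keeps results below 2^31 - 1.
derive_seed <- function(...) {
  xs <- c(...)
  m <- 2147483647
  s <- 113
  for (x in xs) s <- (s * 69069 + as.numeric(x) %% m) %% m
  as.integer(s)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}
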