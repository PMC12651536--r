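#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

#' Deterministically mix a base seed with integer tags.
#'
#' Keeps the result a positive 32-bit integer so it is always a legal
#' `set.seed()` input.
#' @noRd
mix_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (t in c(tags, 0)) {
    h <- (h * 69069 + as.double(t) * 9973 + 1) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

#' Evaluate code under a temporary RNG seed, restoring global RNG state.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Uniform fan-in initialisation (the conventional scheme for conv/dense
#' layers): draws from U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
#' @noRd
init_uniform <- function(dims, fan_in) {
  b <- 1 / sqrt(fan_in)
  array(runif(prod(dims), -b, b), dim = dims)
}

is_odd <- function(k) k %% 2 == 1
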