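#' @keywords internal
#' @useDynLib twinbrain, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded operations inside
#' the package do not disturb the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_ifnot <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
}

#' Stable log(1 + exp(u))
#' @param u numeric vector.
#' @return numeric vector, softplus of `u`.
#' @keywords internal
softplus <- function(u) {
  out <- u
  small <- u < 30
  out[small] <- log1p(exp(u[small]))
  out
}

sigmoid <- function(u) 1 / (1 + exp(-u))

# derive a stream seed from a base seed; keeps results < 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}
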