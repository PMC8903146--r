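#' Derive a reproducible child seed from a master seed
#'
#' Deterministically maps a master seed plus one or more integer indices
#' (iteration number, design-cell index, run number, ...) to a new seed in
#' `[0, 2^31 - 2]`, so that every stochastic component of a sweep or
#' simulation study has its own reproducible stream.
#'
#' @param seed master integer seed.
#' @param ... integer indices identifying the component.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# numerically safe log(1 + exp(z))
log1pexp <- function(z) {
  out <- z
  small <- z < 33
  out[small] <- log1p(exp(z[small]))
  out
}

# sign with explicit zero handling kept (base sign already returns 0)
`%||%` <- function(a, b) if (is.null(a)) b else a
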