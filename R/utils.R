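#' @keywords internal
"_PACKAGE"

#' @useDynLib enteromap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median quantile sd dnorm rnorm runif rpois rbinom coef lm fitted
#' @importFrom utils head tail
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Derive independent substream seeds from one master seed. Substream k of a
# master seed is stable regardless of how many substreams are requested.
derive_seeds <- function(seed, n) {
  # splitmix-style integer scramble, kept within the signed 32-bit range
  s <- (as.double(seed) + 1) %% 2147483647
  out <- numeric(n)
  for (k in seq_len(n)) {
    s <- (s * 69069 + 362437 + k * 9973) %% 2147483647
    out[k] <- s
  }
  as.integer(out)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort(sprintf("`%s` must be a single positive number", name))
  invisible(x)
}
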