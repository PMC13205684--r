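#' @keywords internal
"_PACKAGE"

SPEED_OF_LIGHT <- 299792458

#' Derive a child RNG seed from a parent seed and a stream label
#'
#' Keeps every stochastic stage of the pipeline independently reproducible
#' from one top-level seed without sharing RNG streams. Result is always a
#' valid 32-bit integer seed.
#'
#' @param seed integer parent seed.
#' @param ... labels (strings/integers) identifying the sub-stream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  # polynomial rolling hash, kept inside 2^31 - 1
  h <- 0
  for (code in utf8ToInt(labels)) h <- (h * 131 + code) %% 2147483647L
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("non-finite values in %s", what)
  invisible(x)
}

#' Linear resampling of a regularly sampled series to a new length
#' @keywords internal
resample_linear <- function(x, n_out) {
  n_in <- length(x)
  if (n_in == n_out) return(x)
  stats::approx(seq(0, 1, length.out = n_in), x,
                xout = seq(0, 1, length.out = n_out))$y
}

#' @useDynLib radiosem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
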