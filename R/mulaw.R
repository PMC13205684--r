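#' Mu-law companding of waveform amplitudes
#'
#' `mulaw_encode` maps `x` in `[-1, 1]` through the odd, strictly monotone
#' compander `sign(x) * log(1 + mu * |x|) / log(1 + mu)`; `mulaw_decode`
#' inverts it exactly. Values outside `[-1, 1]` are clipped with a warning.
#'
#' @param x numeric vector/matrix in `[-1, 1]`.
#' @param mu compander parameter (> 0; default 255, the standard telephony
#'   constant).
#' @return companded (or decoded) values, same shape as `x`.
#' @export
mulaw_encode <- function(x, mu = 255) {
  if (mu <= 0) stopf("mu must be > 0")
  if (any(abs(x) > 1)) {
    warnf("mulaw_encode: %d values outside [-1, 1] clipped", sum(abs(x) > 1))
    x <- pmin(pmax(x, -1), 1)
  }
  sign(x) * log1p(mu * abs(x)) / log1p(mu)
}

#' @rdname mulaw_encode
#' @export
mulaw_decode <- function(x, mu = 255) {
  if (mu <= 0) stopf("mu must be > 0")
  sign(x) * (expm1(abs(x) * log1p(mu))) / mu
}

#' Closed-form KL divergence of a diagonal Gaussian from N(0, I)
#'
#' `KL(N(mu, diag(exp(logvar))) || N(0, I)) =
#'  0.5 * sum(mu^2 + exp(logvar) - 1 - logvar)` per row.
#'
#' @param mean,logvar matrices (samples x dims) or vectors.
#' @return numeric vector of per-sample KL values (nats).
#' @export
kl_diag_gaussian <- function(mean, logvar) {
  if (is.null(dim(mean))) mean <- matrix(mean, 1)
  if (is.null(dim(logvar))) logvar <- matrix(logvar, 1)
  rowSums(0.5 * (mean^2 + exp(logvar) - 1 - logvar))
}
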