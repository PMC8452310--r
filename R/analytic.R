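#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Computes the discrete analytic signal `x + i H(x)` of a real vector by
#' zeroing the negative-frequency half of its spectrum and doubling the
#' positive half. The instantaneous phase and envelope of a band-limited
#' signal are the argument and modulus of this analytic signal.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @examples
#' t <- seq(0, 1, by = 1/256)
#' z <- analyticSignal(cos(2 * pi * 13 * t))
#' # envelope of a pure sinusoid is ~1 away from the edges
#' range(Mod(z[30:220]))
#' @export
analyticSignal <- function(x) {
  if (!is.numeric(x)) stop("x must be a real numeric vector")
  n <- length(x)
  if (n == 0L) return(complex(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited signal
#'
#' Argument of the analytic signal, in radians in `(-pi, pi]`. Apply to a
#' band-pass filtered trace; broadband input has no meaningful single phase.
#'
#' @param x real numeric vector (band-limited).
#' @return numeric vector of wrapped phases.
#' @export
instantaneousPhase <- function(x) Arg(analyticSignal(x))

#' Hilbert envelope of a band-limited signal
#'
#' Modulus of the analytic signal.
#'
#' @param x real numeric vector (band-limited).
#' @return numeric vector of envelope amplitudes (same units as `x`).
#' @export
hilbertEnvelope <- function(x) Mod(analyticSignal(x))
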