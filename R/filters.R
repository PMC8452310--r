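# Band-pass filtering for slow-wave and spindle detection.
#
# Both bands use a symmetric (linear-phase) windowed-sinc FIR applied once
# with exact group-delay compensation, which is zero-phase for event timing.
# Because a windowed design puts the cutoff frequency at about -6 dB, the
# design cutoffs are calibrated by bisection so that the realized -3 dB
# points land on the requested band edges.

.filterCache <- new.env(parent = emptyenv())

# |H(f)| of FIR coefficients b at frequency f (Hz) for sampling rate sr.
.firResponseAt <- function(b, f, sr) {
  k <- seq_along(b) - 1
  vapply(f, function(fi) Mod(sum(b * exp(-2i * pi * fi * k / sr))), numeric(1))
}

# Find the design cutoff placing the realized -3 dB point at `target` Hz.
.calibrateEdge <- function(target, side, otherCutoff, taps, sr, transition) {
  nyq <- sr / 2
  lo <- max(target - transition, 1e-4)
  hi <- min(target + transition, nyq * 0.999)
  g <- function(cut) {
    w <- if (side == "low") c(cut, otherCutoff) else c(otherCutoff, cut)
    b <- signal::fir1(taps - 1L, w / nyq, type = "pass")
    .firResponseAt(b, target, sr) - 1 / sqrt(2)
  }
  stats::uniroot(g, lower = lo, upper = hi, tol = 1e-5)$root
}

#' Design a linear-phase band-pass FIR with calibrated -3 dB edges
#'
#' Windowed-sinc (Hamming) FIR whose measured half-power points sit at the
#' requested band edges. The filter length is chosen from the transition
#' width (approximately `3.3 * sr / transition` taps, forced odd), giving
#' > 50 dB stopband attenuation one transition width beyond each edge.
#'
#' @param sr sampling rate in Hz.
#' @param low,high -3 dB band edges in Hz; `high` must be below Nyquist.
#' @param transition transition bandwidth in Hz.
#' @return numeric vector of FIR coefficients (odd length, symmetric).
#' @export
designBandpassFIR <- function(sr, low, high, transition) {
  if (high >= sr / 2) stop("upper band edge must be below the Nyquist frequency")
  if (low <= 0 || low >= high) stop("band edges must satisfy 0 < low < high")
  key <- paste(sr, low, high, transition, sep = "|")
  hit <- .filterCache[[key]]
  if (!is.null(hit)) return(hit)
  taps <- ceiling(3.3 * sr / transition)
  if (taps %% 2 == 0) taps <- taps + 1L
  nyq <- sr / 2
  cl <- low
  ch <- high
  # two alternating passes; the edges are far apart so coupling is tiny
  for (i in 1:2) {
    cl <- .calibrateEdge(low, "low", ch, taps, sr, transition)
    ch <- .calibrateEdge(high, "high", cl, taps, sr, transition)
  }
  b <- signal::fir1(taps - 1L, c(cl, ch) / nyq, type = "pass")
  b <- as.numeric(b)
  .filterCache[[key]] <- b
  b
}

# Apply a symmetric FIR with group-delay compensation (true zero phase).
.filterZeroPhase <- function(b, x) {
  gd <- (length(b) - 1L) / 2L
  y <- signal::fftfilt(b, c(x, numeric(gd)))
  y[(gd + 1L):(gd + length(x))]
}

.resolveSignal <- function(x, sr) {
  if (is(x, "EEGRecording")) list(sig = signalMatrix(x), sr = samplingRate(x))
  else {
    if (is.null(sr)) stop("sr is required when x is not an EEGRecording")
    list(sig = if (is.matrix(x)) x else matrix(x, nrow = 1L), sr = sr)
  }
}

.bandpassApply <- function(x, sr, low, high, transition) {
  r <- .resolveSignal(x, sr)
  b <- designBandpassFIR(r$sr, low, high, transition)
  if (length(b) >= ncol(r$sig))
    stop("signal too short for the requested filter (", length(b), " taps)")
  out <- t(apply(r$sig, 1L, function(ch) .filterZeroPhase(b, ch)))
  dimnames(out) <- dimnames(r$sig)
  if (!is.matrix(x) && !is(x, "EEGRecording")) drop(out) else out
}

#' Delta-band filter for slow-wave detection
#'
#' Zero-phase band-pass used before slow-wave detection: -3 dB at the band
#' edges (0.3 and 4.0 Hz by default) and more than 23 dB attenuation at
#' 0.1 and 4.2 Hz.
#'
#' @param x an [EEGRecording], a channels-x-samples matrix, or a vector.
#' @param low,high -3 dB band edges in Hz.
#' @param sr sampling rate in Hz (ignored when `x` is an [EEGRecording]).
#' @param transition transition bandwidth in Hz.
#' @return filtered signal with the shape of the input.
#' @export
bandpassDelta <- function(x, low = 0.3, high = 4.0, sr = NULL,
                          transition = 0.2) {
  .bandpassApply(x, sr, low, high, transition)
}

#' Sigma-band filter for spindle detection
#'
#' Linear-phase FIR band-pass (10-16 Hz, -3 dB at the edges), applied with
#' group-delay compensation so detected event times are not shifted.
#'
#' @inheritParams bandpassDelta
#' @return filtered signal with the shape of the input.
#' @export
bandpassSigma <- function(x, low = 10, high = 16, sr = NULL,
                          transition = 2) {
  .bandpassApply(x, sr, low, high, transition)
}

#' Delta-band filter for per-wave phase estimation
#'
#' Band used to derive the internal Hilbert phase of each slow wave
#' (0.16-4 Hz); slightly wider at the low end than the detection band so the
#' slowest waves keep a full phase cycle.
#'
#' @inheritParams bandpassDelta
#' @return filtered signal with the shape of the input.
#' @export
bandpassPhaseBand <- function(x, low = 0.16, high = 4.0, sr = NULL,
                              transition = 0.2) {
  .bandpassApply(x, sr, low, high, transition)
}
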