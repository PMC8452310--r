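# Per-wave time-to-phase maps and transition metrics.
#
# Each slow wave's internal phase is the unwrapped instantaneous phase of
# the phase-band (0.16-4 Hz) analytic signal over the wave, offset so that
# phase 0 falls at the depolarization maximum. Over one wave the phase then
# spans [-3*pi/2, pi/2]: -3*pi/2 at the opening negative-going zero
# crossing, -pi at the hyperpolarization trough and +pi/2 at the closing
# crossing.

.PHASE_LO <- -3 * pi / 2
.PHASE_HI <- pi / 2

# Build a PhaseMap from a channel's wrapped instantaneous phase series.
.phaseMapFromWrapped <- function(wrapped, wave, sr, tol = 0.2) {
  i0 <- max(1L, floor(wave$start_s * sr) + 1L)
  i1 <- min(length(wrapped), ceiling(wave$end_s * sr) + 1L)
  idx <- i0:i1
  times <- (idx - 1) / sr
  ph <- unwrapPhase(wrapped[idx])
  iZero <- which.min(abs(times - wave$pos_peak_time))
  ph <- ph - ph[iZero]
  ok <- TRUE
  d <- diff(ph)
  if (length(d) && min(d) < -tol) ok <- FALSE
  if (min(ph) < .PHASE_LO - 2 * tol || max(ph) > .PHASE_HI + 2 * tol) ok <- FALSE
  ph <- pmin(pmax(ph, .PHASE_LO), .PHASE_HI)
  ph <- cummax(ph)   # enforce monotone non-decreasing for inversion
  new("PhaseMap", times = times, phases = ph,
      zeroTime = times[iZero], ok = ok)
}

#' Compute the time-to-phase map of one slow wave
#'
#' Filters the channel in the phase band, takes the Hilbert (analytic)
#' instantaneous phase over a window extending one wave length beyond the
#' wave on each side (to keep edge transients away from the wave), unwraps
#' it, anchors phase 0 at the depolarization maximum and validates the
#' result against the admissible range \eqn{[-3\pi/2, \pi/2]}. A wave whose
#' unwrapped phase is non-monotone or out of range beyond tolerance is
#' flagged (`ok = FALSE`) rather than dropped.
#'
#' @param signal raw (or already phase-band filtered) samples of the wave's
#'   channel, full recording length.
#' @param wave one-row data.frame from [detectSlowWaves()].
#' @param sr sampling rate in Hz.
#' @param band phase band in Hz.
#' @param prefiltered set `TRUE` when `signal` is already band-limited.
#' @return a [PhaseMap] object.
#' @export
computePhaseMap <- function(signal, wave, sr, band = c(0.16, 4.0),
                            prefiltered = FALSE) {
  n <- length(signal)
  i0 <- floor(wave$start_s * sr) + 1L
  i1 <- ceiling(wave$end_s * sr) + 1L
  if (i0 < 1L || i1 > n)
    stop("wave interval lies outside the signal")
  filt <- if (prefiltered) signal
          else bandpassPhaseBand(signal, band[1], band[2], sr = sr)
  # analytic signal over the wave extended by one wave length each side
  span <- i1 - i0 + 1L
  j0 <- i0 - span
  j1 <- i1 + span
  if (j0 < 1L || j1 > n)
    stop("wave too close to the signal edge for phase estimation")
  wrapped <- rep(NA_real_, n)
  wrapped[j0:j1] <- instantaneousPhase(filt[j0:j1])
  .phaseMapFromWrapped(wrapped, wave, sr)
}

#' Transition delay of a slow wave
#'
#' Delay from the maximum negative point (hyperpolarization trough) to the
#' maximum positive point (depolarization peak) of the wave.
#'
#' @param wave one-row data.frame (or list) with `neg_peak_time` and
#'   `pos_peak_time` in seconds.
#' @return tau in seconds (positive).
#' @export
transitionDelay <- function(wave) {
  tau <- wave$pos_peak_time - wave$neg_peak_time
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("positive peak must follow the negative peak (detection inconsistency)")
  tau
}

#' Transition frequency of a slow wave
#'
#' The frequency of the half-wave spanned by the depolarization transition:
#' `f_tau = 1 / (2 * tau)`. A wave taking 200 ms to swing from trough to
#' peak has a transition frequency of 2.5 Hz.
#'
#' @param tau transition delay in seconds (positive).
#' @return transition frequency in Hz.
#' @examples
#' transitionFrequency(0.2)   # 2.5 Hz
#' transitionFrequency(0.5)   # 1.0 Hz
#' @export
transitionFrequency <- function(tau) {
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("tau must be positive")
  1 / (2 * tau)
}

#' Overall slow-wave frequency
#'
#' Inverse of the total wave duration T (opening to closing negative-going
#' zero crossing). Equals the transition frequency only for waves with
#' equal-duration lobes.
#'
#' @param wave one-row data.frame (or list) with column `T_s`, or a numeric
#'   duration in seconds.
#' @return frequency in Hz.
#' @export
waveFrequency <- function(wave) {
  T <- if (is.numeric(wave)) wave else wave$T_s
  if (any(!is.finite(T)) || any(T <= 0)) stop("total duration T must be positive")
  1 / T
}

#' Sample the six connectivity phase points of a wave
#'
#' Five phases evenly spaced along the depolarization transition, from the
#' hyperpolarization trough (-pi) to the depolarization maximum (0), plus a
#' sixth phase after the maximum (+pi/4 by default):
#' \{-pi, -3pi/4, -pi/2, -pi/4, 0, +pi/4\}. Times are obtained by inverting
#' the wave's phase map; a phase not covered by the map yields `NA` time
#' (the wave is excluded from that phase point only).
#'
#' @param phaseMap a [PhaseMap].
#' @param phases named numeric vector of target phases in radians.
#' @return data.frame with columns `label`, `phase`, `time`.
#' @export
samplePhasePoints <- function(phaseMap,
                              phases = c(a = -pi, b = -3 * pi / 4,
                                         c = -pi / 2, d = -pi / 4,
                                         e = 0, f = pi / 4)) {
  ph <- phaseMap@phases
  tt <- phaseMap@times
  # invert the monotone map; drop duplicated plateau values
  keep <- c(TRUE, diff(ph) > 0)
  times <- stats::approx(ph[keep], tt[keep], xout = phases, rule = 1)$y
  data.frame(label = names(phases), phase = as.numeric(phases),
             time = times, stringsAsFactors = FALSE)
}
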