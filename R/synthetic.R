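# Seeded synthetic polysomnography with ground-truth annotations.
#
# The generator embodies the statistical structure the downstream analysis
# assumes: 1/f background EEG on a 10-20 montage, biphasic slow waves whose
# transition delay tau is drawn from a two-mode distribution (slow and fast
# switchers), optional spindles phase-coupled to the waves, a constant
# per-channel propagation lag that creates detectable phase-locked
# connectivity, and per-cycle event rates decaying exponentially across
# cycles. All randomness derives from one master seed through a documented
# splitting scheme (see `splitSeed`), so identical configs give
# bit-identical output.

.MONTAGE19 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
                "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

#' Configuration of the synthetic polysomnography generator
#'
#' Defaults give a 19-channel, 256 Hz night of three compressed sleep
#' cycles whose injected slow waves satisfy the detection criteria and
#' whose transition-frequency modes sit on either side of 1.2 Hz
#' (slow switchers near 0.9 Hz, fast switchers near 1.8 Hz). The per-class
#' event rates decay as `exp(-r * (cycle - 1))` with the class-specific
#' rates `decayRateSlow`/`decayRateFast`.
#'
#' @param nChannels number of channels (10-20 labels; 19 by default).
#' @param samplingRate sampling rate in Hz (>= 128).
#' @param nCycles number of sleep cycles.
#' @param cycleMinutes minutes per cycle (80% NREM, 20% REM).
#' @param swRateCycle1 slow-wave rate in events/min per switcher class in
#'   cycle 1 (over NREM time).
#' @param decayRateSlow,decayRateFast unitless exponential rates r per
#'   cycle driving the across-cycle decline of each class.
#' @param tauModeSlow,tauModeFast means (s) of the two transition-delay
#'   populations.
#' @param tauSdSlow,tauSdFast standard deviations (s) of the two
#'   populations.
#' @param swAmplitude slow-wave peak-to-peak amplitude in microvolts.
#' @param spindleProbability fraction of slow waves carrying a coupled
#'   spindle.
#' @param spindleAmplitude spindle amplitude in microvolts.
#' @param channelLag constant propagation lag in seconds added per channel
#'   index (channel j leads channel j+1 by `channelLag`).
#' @param noiseExponent slope of the 1/f^a background spectrum.
#' @param noiseSd broadband background standard deviation in microvolts.
#' @param seed master integer seed.
#' @return validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nChannels = 19, samplingRate = 256, nCycles = 3,
                            cycleMinutes = 20, swRateCycle1 = 2.5,
                            decayRateSlow = 1.3, decayRateFast = 1.6,
                            tauModeSlow = 0.55, tauModeFast = 0.28,
                            tauSdSlow = 0.10, tauSdFast = 0.04,
                            swAmplitude = 120, spindleProbability = 0.5,
                            spindleAmplitude = 30, channelLag = 0.01,
                            noiseExponent = 1, noiseSd = 15, seed = 1) {
  cfg <- list(nChannels = as.integer(nChannels), samplingRate = samplingRate,
              nCycles = as.integer(nCycles), cycleMinutes = cycleMinutes,
              swRateCycle1 = swRateCycle1, decayRateSlow = decayRateSlow,
              decayRateFast = decayRateFast, tauModeSlow = tauModeSlow,
              tauModeFast = tauModeFast, tauSdSlow = tauSdSlow,
              tauSdFast = tauSdFast, swAmplitude = swAmplitude,
              spindleProbability = spindleProbability,
              spindleAmplitude = spindleAmplitude, channelLag = channelLag,
              noiseExponent = noiseExponent, noiseSd = noiseSd,
              seed = as.integer(seed))
  if (cfg$samplingRate < 128) stop("samplingRate must be >= 128 Hz")
  if (cfg$nChannels < 1) stop("at least one channel is required")
  if (cfg$nCycles < 1 || cfg$cycleMinutes <= 0)
    stop("cycle structure must have positive duration")
  if (cfg$swRateCycle1 < 0 || cfg$decayRateSlow < 0 || cfg$decayRateFast < 0)
    stop("rates must be non-negative")
  if (cfg$tauModeSlow <= 0 || cfg$tauModeFast <= 0 ||
      cfg$tauSdSlow < 0 || cfg$tauSdFast < 0)
    stop("transition-delay parameters must be positive")
  if (cfg$swAmplitude < 0 || cfg$spindleAmplitude < 0 || cfg$noiseSd < 0)
    stop("amplitudes must be non-negative")
  if (cfg$spindleProbability < 0 || cfg$spindleProbability > 1)
    stop("spindleProbability must lie in [0, 1]")
  class(cfg) <- "SyntheticConfig"
  cfg
}

# 1/f^a background noise via spectral shaping of white noise.
.pinkNoise <- function(n, exponent, sd) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k)          # symmetric frequency index
  mag <- c(0, freq[-1]^(-exponent / 2))
  x <- Re(stats::fft(W * mag, inverse = TRUE) / n)
  x * sd / stats::sd(x)
}

#' Biphasic slow-wave template
#'
#' Half-cosine negative lobe followed by a half-cosine positive lobe with
#' independently settable lobe durations. The trough sits at the centre of
#' the negative lobe and the peak at the centre of the positive lobe, so
#' the trough-to-peak delay is `(negDuration + posDuration) / 2`; with the
#' default equal lobes this equals `tau`.
#'
#' @param tau transition delay in seconds (> 0).
#' @param amplitude peak-to-peak amplitude in microvolts.
#' @param sr sampling rate in Hz.
#' @param negDuration,posDuration lobe durations in seconds; their mean
#'   must equal `tau` within one sample.
#' @param negFraction fraction of the peak-to-peak amplitude carried by the
#'   negative lobe.
#' @return list with `samples` (the waveform, starting at the opening zero
#'   crossing) and `zeroCrossOffset` (s from waveform start to the
#'   negative-to-positive zero crossing).
#' @export
slowWaveTemplate <- function(tau, amplitude, sr, negDuration = tau,
                             posDuration = tau, negFraction = 0.55) {
  if (tau <= 0) stop("tau must be positive")
  if (abs((negDuration + posDuration) / 2 - tau) > 1 / sr)
    stop("lobe durations are inconsistent with tau: trough-to-peak delay is ",
         "(negDuration + posDuration) / 2")
  nNeg <- round(negDuration * sr)
  nPos <- round(posDuration * sr)
  tNeg <- seq_len(nNeg) / sr
  tPos <- seq_len(nPos) / sr
  wave <- c(-negFraction * amplitude * sin(pi * tNeg / negDuration),
            (1 - negFraction) * amplitude * sin(pi * tPos / posDuration))
  list(samples = wave, zeroCrossOffset = nNeg / sr)
}

#' Inject a slow wave into a channel signal
#'
#' Adds the biphasic template of [slowWaveTemplate()] to `signal`, with the
#' negative-to-positive zero crossing at `tCenter`. The trough-to-peak
#' delay of the injected waveform equals `tau` within one sample.
#'
#' @param signal numeric vector of channel samples.
#' @param tCenter time (s) of the negative-to-positive zero crossing.
#' @param tau transition delay in seconds.
#' @param amplitude peak-to-peak amplitude in microvolts; 0 leaves the
#'   signal unchanged.
#' @param sr sampling rate in Hz.
#' @param ... further arguments to [slowWaveTemplate()].
#' @return the signal with the wave added.
#' @export
injectSlowWave <- function(signal, tCenter, tau, amplitude, sr, ...) {
  if (tau <= 0) stop("tau must be positive")
  tpl <- slowWaveTemplate(tau, amplitude, sr, ...)
  start <- round((tCenter - tpl$zeroCrossOffset) * sr) + 1L
  idx <- start:(start + length(tpl$samples) - 1L)
  if (idx[1] < 1L || idx[length(idx)] > length(signal))
    stop("slow wave does not fit inside the signal")
  signal[idx] <- signal[idx] + tpl$samples
  signal
}

#' Inject a spindle into a channel signal
#'
#' Hann-windowed sinusoidal burst (13 Hz by default).
#'
#' @param signal numeric vector of channel samples.
#' @param tOnset burst onset time in seconds.
#' @param duration burst duration in seconds.
#' @param amplitude peak amplitude in microvolts.
#' @param sr sampling rate in Hz.
#' @param freq oscillation frequency in Hz.
#' @return the signal with the burst added.
#' @export
injectSpindle <- function(signal, tOnset, duration, amplitude, sr,
                          freq = 13) {
  if (duration <= 0) stop("duration must be positive")
  n <- round(duration * sr)
  t <- seq_len(n) / sr
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  burst <- amplitude * hann * sin(2 * pi * freq * t)
  start <- round(tOnset * sr) + 1L
  idx <- start:(start + n - 1L)
  if (idx[1] < 1L || idx[length(idx)] > length(signal))
    stop("spindle does not fit inside the signal")
  signal[idx] <- signal[idx] + burst
  signal
}

# Deterministic block hypnogram: per cycle 25% N2, 55% N3, 20% REM.
.blockHypnogram <- function(cfg) {
  epochsPerCycle <- round(cfg$cycleMinutes * 60 / 30)
  nN2 <- round(0.25 * epochsPerCycle)
  nR <- round(0.20 * epochsPerCycle)
  nN3 <- epochsPerCycle - nN2 - nR
  stages <- rep(c(rep("N2", nN2), rep("N3", nN3), rep("R", nR)), cfg$nCycles)
  cyc <- rep(seq_len(cfg$nCycles), each = epochsPerCycle)
  Hypnogram(stages, cycleIndex = cyc)
}

#' Generate a synthetic polysomnography recording
#'
#' Builds the background EEG, hypnogram and ground-truth annotations from a
#' [syntheticConfig()]. Slow-wave events are global: each event appears on
#' every channel, time-shifted by the cumulative per-channel propagation
#' lag, so each event is detectable on each channel and every channel pair
#' has a constant non-vanishing delay (the structure the phase lag index is
#' sensitive to). Event counts per class and cycle are Poisson with mean
#' `swRateCycle1 * nremMinutes * exp(-r * (cycle - 1))`.
#'
#' @param config a [syntheticConfig()].
#' @return list with elements `recording` ([EEGRecording]), `hypnogram`
#'   ([Hypnogram]) and `groundTruth` (list of `slowWaveEvents`,
#'   `spindleEvents` data.frames and the `cycleBoundaries` epoch table).
#' @export
generateRecording <- function(config) {
  if (!inherits(config, "SyntheticConfig"))
    config <- do.call(syntheticConfig, config)
  cfg <- config
  sr <- cfg$samplingRate
  hyp <- .blockHypnogram(cfg)
  nSamp <- cfg$nCycles * round(cfg$cycleMinutes * 60) * sr
  labels <- if (cfg$nChannels <= length(.MONTAGE19))
    .MONTAGE19[seq_len(cfg$nChannels)]
  else c(.MONTAGE19, paste0("x", seq_len(cfg$nChannels - length(.MONTAGE19))))
  lag <- (seq_len(cfg$nChannels) - 1L) * cfg$channelLag

  epochsPerCycle <- round(cfg$cycleMinutes * 60 / 30)
  cleanEpoch <- cleanNremEpochs(hyp)

  # --- event schedule (substream 1) ---------------------------------------
  margin <- 3  # s, keeps full waveform + lags inside NREM blocks
  minSep <- 4  # s between event centres across the montage
  events <- with_seed(splitSeed(cfg$seed, 1L), {
    rows <- list()
    eid <- 0L
    for (cyc in seq_len(cfg$nCycles)) {
      eps <- which(cycleIndices(hyp) == cyc & cleanEpoch)
      if (!length(eps)) next
      nremMin <- length(eps) * epochLength(hyp) / 60
      lo <- (min(eps) - 1) * epochLength(hyp) + margin
      hi <- max(eps) * epochLength(hyp) - margin - max(lag)
      for (class in c("slow", "fast")) {
        r <- if (class == "slow") cfg$decayRateSlow else cfg$decayRateFast
        lambda <- cfg$swRateCycle1 * nremMin * exp(-r * (cyc - 1))
        nEv <- stats::rpois(1, lambda)
        if (nEv == 0) next
        tauMu <- if (class == "slow") cfg$tauModeSlow else cfg$tauModeFast
        tauSd <- if (class == "slow") cfg$tauSdSlow else cfg$tauSdFast
        placed <- numeric(0)
        for (k in seq_len(nEv)) {
          for (try in 1:200) {
            tc <- stats::runif(1, lo, hi)
            if (!length(placed) || min(abs(placed - tc)) >= minSep) break
            tc <- NA_real_
          }
          if (!is.finite(tc)) next
          placed <- c(placed, tc)
          tau <- min(max(stats::rnorm(1, tauMu, tauSd), 0.15), 0.9)
          eid <- eid + 1L
          rows[[eid]] <- data.frame(event_id = eid, cycle = cyc,
                                    class = class, t_center = tc, tau = tau,
                                    stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
  if (is.null(events))
    events <- data.frame(event_id = integer(), cycle = integer(),
                         class = character(), t_center = numeric(),
                         tau = numeric(), stringsAsFactors = FALSE)

  # --- spindle coupling (substream 2) -------------------------------------
  spindleDraws <- with_seed(splitSeed(cfg$seed, 2L), {
    if (!nrow(events)) data.frame()
    else data.frame(
      coupled = stats::runif(nrow(events)) < cfg$spindleProbability,
      duration = stats::runif(nrow(events), 0.5, 1.5))
  })

  # --- background noise (substreams 100 + channel) ------------------------
  sig <- matrix(0, cfg$nChannels, nSamp, dimnames = list(labels, NULL))
  if (cfg$noiseSd > 0) {
    for (ch in seq_len(cfg$nChannels))
      sig[ch, ] <- with_seed(splitSeed(cfg$seed, 100L + ch),
                             .pinkNoise(nSamp, cfg$noiseExponent, cfg$noiseSd))
  }

  # --- inject events ------------------------------------------------------
  swRows <- vector("list", nrow(events) * max(cfg$nChannels, 1L))
  spRows <- list()
  ri <- 0L
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    for (ch in seq_len(cfg$nChannels)) {
      tc <- ev$t_center + lag[ch]
      if (cfg$swAmplitude > 0)
        sig[ch, ] <- injectSlowWave(sig[ch, ], tc, ev$tau, cfg$swAmplitude, sr)
      ri <- ri + 1L
      swRows[[ri]] <- data.frame(
        event_id = ev$event_id, channel = labels[ch],
        neg_peak_time = tc - ev$tau / 2, pos_peak_time = tc + ev$tau / 2,
        tau = ev$tau, class = ev$class, cycle = ev$cycle,
        stringsAsFactors = FALSE)
      if (nrow(spindleDraws) && spindleDraws$coupled[i] &&
          cfg$spindleAmplitude > 0) {
        # onset at wave phase -pi/4: a quarter of the positive lobe after
        # the zero crossing (linear-phase approximation on the template)
        onset <- tc + ev$tau / 4
        dur <- spindleDraws$duration[i]
        if (round((onset + dur) * sr) < nSamp) {
          sig[ch, ] <- injectSpindle(sig[ch, ], onset, dur,
                                     cfg$spindleAmplitude, sr)
          spRows[[length(spRows) + 1L]] <- data.frame(
            event_id = ev$event_id, channel = labels[ch], onset = onset,
            offset = onset + dur, stringsAsFactors = FALSE)
        }
      }
    }
  }
  swEvents <- do.call(rbind, swRows[seq_len(ri)])
  if (is.null(swEvents))
    swEvents <- data.frame(event_id = integer(), channel = character(),
                           neg_peak_time = numeric(), pos_peak_time = numeric(),
                           tau = numeric(), class = character(),
                           cycle = integer(), stringsAsFactors = FALSE)
  spEvents <- if (length(spRows)) do.call(rbind, spRows)
              else data.frame(event_id = integer(), channel = character(),
                              onset = numeric(), offset = numeric(),
                              stringsAsFactors = FALSE)
  cycleBounds <- data.frame(
    cycle = seq_len(cfg$nCycles),
    first_epoch = (seq_len(cfg$nCycles) - 1L) * epochsPerCycle + 1L,
    last_epoch = seq_len(cfg$nCycles) * epochsPerCycle)
  list(recording = EEGRecording(sig, sr, labels),
       hypnogram = hyp,
       groundTruth = list(slowWaveEvents = swEvents,
                          spindleEvents = spEvents,
                          cycleBoundaries = cycleBounds,
                          config = unclass(cfg)))
}
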