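# Slow-wave detection on the delta-filtered signal.
#
# Candidate waves are delimited by successive negative-going zero crossings;
# the negative deflection runs to the next positive-going crossing and the
# positive deflection covers the remainder. A candidate becomes a slow wave
# when all four amplitude/duration criteria hold and the wave lies entirely
# inside artifact-free N2/N3 epochs.

.checkAlignment <- function(nSamples, hypnogram, sr) {
  cover <- nEpochs(hypnogram) * epochLength(hypnogram) * sr
  if (nSamples > cover || nSamples <= cover - epochLength(hypnogram) * sr)
    stop("hypnogram does not align with the signal: ", nSamples,
         " samples vs ", cover, " covered by ", nEpochs(hypnogram), " epochs")
  invisible(TRUE)
}

# Epoch index (1-based) containing time t (seconds from recording start).
.epochOfTime <- function(t, hypnogram) {
  pmin(floor(t / epochLength(hypnogram)) + 1L, nEpochs(hypnogram))
}

#' Artifact-free NREM epochs
#'
#' Logical per-epoch mask marking artifact-free N2/N3 epochs, the scoring
#' support for all event detection and densities.
#'
#' @param hypnogram a [Hypnogram].
#' @return logical vector, one element per epoch.
#' @export
cleanNremEpochs <- function(hypnogram) {
  stages(hypnogram) %in% c("N2", "N3") & !artifactMask(hypnogram)
}

# Interpolated zero-crossing times (s, 0-based) of one direction.
.zeroCrossings <- function(x, sr, direction = c("down", "up")) {
  direction <- match.arg(direction)
  n <- length(x)
  a <- x[-n]
  b <- x[-1L]
  idx <- if (direction == "down") which(a > 0 & b <= 0) else which(a < 0 & b >= 0)
  (idx - 1 + a[idx] / (a[idx] - b[idx])) / sr
}

#' Detect slow waves on a delta-filtered signal
#'
#' Applies the four amplitude/duration criteria to zero-crossing-delimited
#' candidate waves of the delta-filtered trace: negative peak below
#' `negPeakMax` microvolts, peak-to-peak amplitude above `p2pMin`, negative
#' deflection lasting `negDurRange` seconds (inclusive) and positive
#' deflection no longer than `posDurMax`. Only waves lying entirely within
#' artifact-free N2/N3 epochs are returned. Peak times are refined by
#' parabolic interpolation, the transition delay is
#' `tau = pos_peak_time - neg_peak_time` and the transition frequency
#' `f_tau = 1 / (2 tau)`.
#'
#' @param filtered delta-filtered signal: channels-x-samples matrix (row
#'   names as channel labels) or a single numeric vector.
#' @param hypnogram a [Hypnogram] aligned with the signal.
#' @param sr sampling rate in Hz.
#' @param negPeakMax negative-peak criterion in microvolts (peak must be
#'   below this value).
#' @param p2pMin peak-to-peak amplitude criterion in microvolts.
#' @param negDurRange allowed negative-deflection duration, seconds.
#' @param posDurMax maximum positive-deflection duration, seconds.
#' @return data.frame with one row per slow wave: `wave_id`, `channel`,
#'   `start_s`, `end_s`, `neg_peak_time`, `pos_peak_time`, `neg_peak_amp`,
#'   `pos_peak_amp`, `neg_duration`, `pos_duration`, `T_s`, `frequency_hz`,
#'   `tau_s`, `f_tau_hz`, `cycle`, `has_spindle` (NA until
#'   [tagCooccurrence()] runs) and `switcher` (`"unlabeled"`).
#' @export
detectSlowWaves <- function(filtered, hypnogram, sr,
                            negPeakMax = -40, p2pMin = 75,
                            negDurRange = c(0.125, 1.5), posDurMax = 1.0) {
  if (!is.matrix(filtered)) filtered <- matrix(filtered, nrow = 1L)
  .checkAlignment(ncol(filtered), hypnogram, sr)
  labels <- rownames(filtered) %||% paste0("ch", seq_len(nrow(filtered)))
  cleanEpoch <- cleanNremEpochs(hypnogram)
  out <- vector("list", nrow(filtered))
  for (ch in seq_len(nrow(filtered))) {
    x <- filtered[ch, ]
    down <- .zeroCrossings(x, sr, "down")
    up <- .zeroCrossings(x, sr, "up")
    if (length(down) < 2L) { out[[ch]] <- NULL; next }
    rows <- vector("list", length(down) - 1L)
    for (i in seq_len(length(down) - 1L)) {
      d1 <- down[i]; d2 <- down[i + 1L]
      u <- up[up > d1 & up < d2]
      if (length(u) == 0L) next
      u <- u[1L]                         # first polarity reversal
      negDur <- u - d1
      posDur <- d2 - u
      if (negDur < negDurRange[1] || negDur > negDurRange[2]) next
      if (posDur > posDurMax) next
      iNegLobe <- (floor(d1 * sr) + 1L):(ceiling(u * sr) + 1L)
      iPosLobe <- (floor(u * sr) + 1L):(ceiling(d2 * sr) + 1L)
      iNegLobe <- iNegLobe[iNegLobe >= 1L & iNegLobe <= length(x)]
      iPosLobe <- iPosLobe[iPosLobe >= 1L & iPosLobe <= length(x)]
      iNeg <- iNegLobe[which.min(x[iNegLobe])]
      iPos <- iPosLobe[which.max(x[iPosLobe])]
      negAmp <- x[iNeg]; posAmp <- x[iPos]
      if (!(negAmp < negPeakMax)) next
      if (!(posAmp - negAmp > p2pMin)) next
      # sub-sample refinement of the peak locations
      tNeg <- (iNeg - 1 + parabolicOffset(x, iNeg)) / sr
      tPos <- (iPos - 1 + parabolicOffset(x, iPos)) / sr
      if (tPos <= tNeg) next
      epochs <- .epochOfTime(d1, hypnogram):.epochOfTime(d2, hypnogram)
      if (!all(cleanEpoch[epochs])) next
      tau <- tPos - tNeg
      rows[[i]] <- data.frame(
        channel = labels[ch], start_s = d1, end_s = d2,
        neg_peak_time = tNeg, pos_peak_time = tPos,
        neg_peak_amp = negAmp, pos_peak_amp = posAmp,
        neg_duration = negDur, pos_duration = posDur,
        T_s = d2 - d1, frequency_hz = 1 / (d2 - d1),
        tau_s = tau, f_tau_hz = 1 / (2 * tau),
        cycle = cycleIndices(hypnogram)[.epochOfTime(tNeg, hypnogram)],
        stringsAsFactors = FALSE)
    }
    out[[ch]] <- do.call(rbind, rows)
  }
  waves <- do.call(rbind, out)
  if (is.null(waves))
    waves <- data.frame(channel = character(), start_s = numeric(),
                        end_s = numeric(), neg_peak_time = numeric(),
                        pos_peak_time = numeric(), neg_peak_amp = numeric(),
                        pos_peak_amp = numeric(), neg_duration = numeric(),
                        pos_duration = numeric(), T_s = numeric(),
                        frequency_hz = numeric(), tau_s = numeric(),
                        f_tau_hz = numeric(), cycle = integer(),
                        stringsAsFactors = FALSE)
  waves <- waves[order(waves$channel, waves$start_s), , drop = FALSE]
  rownames(waves) <- NULL
  waves$has_spindle <- rep(NA, nrow(waves))
  waves$switcher <- rep("unlabeled", nrow(waves))
  waves$wave_id <- if (nrow(waves)) seq_len(nrow(waves)) else integer()
  waves
}

#' Slow-wave density in events per minute
#'
#' Number of detected waves per artifact-free N2/N3 minute, per channel or
#' pooled over channel clusters (e.g. frontal = F3, Fz, F4).
#'
#' @param waves data.frame from [detectSlowWaves()].
#' @param hypnogram the aligned [Hypnogram].
#' @param clusters optional named list of channel-label vectors; when given,
#'   events are pooled within each cluster and density is per cluster.
#' @return named numeric vector of densities (events/min).
#' @export
slowWaveDensity <- function(waves, hypnogram, clusters = NULL) {
  minutes <- sum(cleanNremEpochs(hypnogram)) * epochLength(hypnogram) / 60
  if (minutes <= 0) stop("no artifact-free N2/N3 time in the hypnogram")
  if (is.null(clusters)) {
    counts <- table(waves$channel)
    dens <- as.numeric(counts) / minutes
    names(dens) <- names(counts)
  } else {
    dens <- vapply(clusters, function(chs)
      sum(waves$channel %in% chs) / minutes, numeric(1))
  }
  dens
}
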