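# Spindle detection: smoothed Hilbert envelope of the sigma-filtered signal
# thresholded at the channel-wise 75th percentile of artifact-free N2/N3
# samples; supra-threshold runs closer than the merge gap are joined and
# events lasting 0.5-3 s are kept.

# Per-sample logical mask of artifact-free N2/N3 samples.
.cleanNremSamples <- function(hypnogram, nSamples, sr) {
  perEpoch <- cleanNremEpochs(hypnogram)
  rep(perEpoch, each = round(epochLength(hypnogram) * sr))[seq_len(nSamples)]
}

# Centered moving average, edges shortened.
.movingAverage <- function(x, width) {
  if (width <= 1L) return(x)
  k <- rep(1 / width, width)
  y <- stats::filter(x, k, sides = 2)
  # repair the NA edges with partial means
  half <- (width - 1L) %/% 2L
  n <- length(x)
  for (i in which(is.na(y))) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    y[i] <- mean(x[lo:hi])
  }
  as.numeric(y)
}

#' Detect sleep spindles on a sigma-filtered signal
#'
#' The Hilbert-transform envelope of the 10-16 Hz band-limited signal is
#' smoothed with a moving average and thresholded at the channel-wise
#' `percentile` (75th) computed over artifact-free N2/N3 samples. Runs above
#' threshold separated by less than `mergeGap` are merged; events with a
#' duration inside `durRange` (0.5-3 s) and lying within artifact-free
#' N2/N3 epochs are returned.
#'
#' The percentile threshold makes detection scale-covariant: rescaling the
#' signal rescales the threshold and leaves the detections unchanged.
#'
#' @param filteredSigma sigma-filtered signal: channels-x-samples matrix or
#'   a numeric vector.
#' @param hypnogram aligned [Hypnogram].
#' @param sr sampling rate in Hz.
#' @param percentile envelope percentile used as threshold (0-1 scale).
#' @param smoothSec moving-average window for envelope smoothing, seconds.
#' @param mergeGap maximum gap between merged supra-threshold runs, seconds.
#' @param durRange allowed event duration, seconds (inclusive).
#' @return data.frame with columns `channel`, `onset`, `offset`, `duration`
#'   and `peak_envelope`.
#' @export
detectSpindles <- function(filteredSigma, hypnogram, sr,
                           percentile = 0.75, smoothSec = 0.2,
                           mergeGap = 0.1, durRange = c(0.5, 3)) {
  if (!is.matrix(filteredSigma)) filteredSigma <- matrix(filteredSigma, nrow = 1L)
  .checkAlignment(ncol(filteredSigma), hypnogram, sr)
  labels <- rownames(filteredSigma) %||% paste0("ch", seq_len(nrow(filteredSigma)))
  cleanMask <- .cleanNremSamples(hypnogram, ncol(filteredSigma), sr)
  if (!any(cleanMask)) stop("no artifact-free N2/N3 samples in the hypnogram")
  cleanEpoch <- cleanNremEpochs(hypnogram)
  width <- max(1L, round(smoothSec * sr))
  out <- vector("list", nrow(filteredSigma))
  for (ch in seq_len(nrow(filteredSigma))) {
    env <- .movingAverage(hilbertEnvelope(filteredSigma[ch, ]), width)
    thr <- stats::quantile(env[cleanMask], percentile, names = FALSE)
    above <- env > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    if (!length(on)) next
    ev <- data.frame(start = starts[on], end = ends[on])
    # merge runs separated by less than mergeGap
    if (nrow(ev) > 1L) {
      keep <- ev[1L, , drop = FALSE]
      for (i in 2L:nrow(ev)) {
        if ((ev$start[i] - keep$end[nrow(keep)] - 1L) / sr < mergeGap)
          keep$end[nrow(keep)] <- ev$end[i]
        else keep <- rbind(keep, ev[i, ])
      }
      ev <- keep
    }
    onset <- (ev$start - 1) / sr
    offset <- (ev$end - 1) / sr
    dur <- offset - onset
    ok <- dur >= durRange[1] & dur <= durRange[2]
    # events must lie inside artifact-free N2/N3 epochs
    if (any(ok)) {
      inNrem <- vapply(which(ok), function(i) {
        eps <- .epochOfTime(onset[i], hypnogram):.epochOfTime(offset[i], hypnogram)
        all(cleanEpoch[eps])
      }, logical(1))
      ok[ok] <- inNrem
    }
    if (!any(ok)) next
    out[[ch]] <- data.frame(
      channel = labels[ch], onset = onset[ok], offset = offset[ok],
      duration = dur[ok],
      peak_envelope = vapply(which(ok), function(i)
        max(env[ev$start[i]:ev$end[i]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  spindles <- do.call(rbind, out)
  if (is.null(spindles))
    spindles <- data.frame(channel = character(), onset = numeric(),
                           offset = numeric(), duration = numeric(),
                           peak_envelope = numeric(), stringsAsFactors = FALSE)
  rownames(spindles) <- NULL
  spindles
}

#' Tag slow-wave / spindle co-occurrence
#'
#' A slow wave co-occurs with a spindle when a same-channel spindle onset
#' falls at a slow-wave phase inside `window` (\eqn{[-\pi, \pi/2]}). The
#' wave phase at the spindle onset is read off the wave's time-to-phase map
#' computed from the phase-band filtered signal.
#'
#' @param waves data.frame from [detectSlowWaves()].
#' @param spindles data.frame from [detectSpindles()].
#' @param phaseSignal phase-band filtered signal (channels x samples matrix,
#'   e.g. from [bandpassPhaseBand()]) used to build per-wave phase maps.
#' @param sr sampling rate in Hz.
#' @param window phase interval (radians) defining co-occurrence.
#' @return `waves` with its `has_spindle` column filled in.
#' @export
tagCooccurrence <- function(waves, spindles, phaseSignal, sr,
                            window = c(-pi, pi / 2)) {
  if (missing(phaseSignal) || is.null(phaseSignal))
    stop("phaseSignal is required to evaluate slow-wave phase maps")
  if (!is.matrix(phaseSignal)) phaseSignal <- matrix(phaseSignal, nrow = 1L)
  labels <- rownames(phaseSignal) %||% paste0("ch", seq_len(nrow(phaseSignal)))
  waves$has_spindle <- rep(FALSE, nrow(waves))
  if (!nrow(waves) || !nrow(spindles)) return(waves)
  wrapped <- lapply(seq_len(nrow(phaseSignal)), function(ch)
    instantaneousPhase(phaseSignal[ch, ]))
  names(wrapped) <- labels
  for (i in seq_len(nrow(waves))) {
    w <- waves[i, ]
    cand <- spindles[spindles$channel == w$channel &
                     spindles$onset >= w$start_s &
                     spindles$onset <= w$end_s, , drop = FALSE]
    if (!nrow(cand)) next
    pm <- .phaseMapFromWrapped(wrapped[[w$channel]], w, sr)
    ph <- stats::approx(pm@times, pm@phases, xout = cand$onset, rule = 2)$y
    waves$has_spindle[i] <- any(ph >= window[1] & ph <= window[2])
  }
  waves
}
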