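#' @import methods
NULL

#' Multichannel EEG recording
#'
#' Container for a referenced multichannel scalp EEG signal. Rows of the
#' signal matrix are channels (10-20 montage labels), columns are samples in
#' microvolts at a fixed sampling rate.
#'
#' @slot signal numeric matrix, channels x samples, in microvolts.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelLabels character vector of unique channel labels, one per row.
#' @slot reference free-text description of the recording reference.
#'
#' @seealso [EEGRecording()] for the constructor, [generateRecording()] for
#'   the synthetic generator, [readEDF()]/[writeEDF()] for file interchange.
#' @export
setClass("EEGRecording",
  representation(
    signal = "matrix",
    samplingRate = "numeric",
    channelLabels = "character",
    reference = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (nrow(object@signal) != length(object@channelLabels))
    msg <- c(msg, "one channel label per signal row is required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (!is.numeric(object@signal))
    msg <- c(msg, "signal must be numeric")
  if (length(msg)) msg else TRUE
})

#' Hypnogram with cycle indices and artifact mask
#'
#' Per-epoch sleep staging aligned to an [EEGRecording]. Stages use the AASM
#' labels W, N1, N2, N3, R scored in fixed-length epochs (30 s by default).
#' `cycleIndex` assigns each epoch to a sleep cycle (0 = outside any cycle)
#' and `artifact` marks epochs to exclude from all event detection.
#'
#' @slot stages character vector of per-epoch stage labels.
#' @slot cycleIndex integer vector, same length as `stages`.
#' @slot artifact logical vector, same length as `stages`.
#' @slot epochLength epoch duration in seconds.
#'
#' @export
setClass("Hypnogram",
  representation(
    stages = "character",
    cycleIndex = "integer",
    artifact = "logical",
    epochLength = "numeric"
  )
)

setValidity("Hypnogram", function(object) {
  msg <- character()
  ok <- object@stages %in% c("W", "N1", "N2", "N3", "R")
  if (!all(ok))
    msg <- c(msg, sprintf("unknown stage label(s): %s",
                          paste(unique(object@stages[!ok]), collapse = ", ")))
  n <- length(object@stages)
  if (length(object@cycleIndex) != n || length(object@artifact) != n)
    msg <- c(msg, "stages, cycleIndex and artifact must have equal length")
  if (any(object@cycleIndex < 0L))
    msg <- c(msg, "cycle indices must be >= 0")
  if (length(object@epochLength) != 1L || object@epochLength <= 0)
    msg <- c(msg, "epochLength must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Time-to-phase map of a single slow wave
#'
#' Maps the time axis of one detected slow wave onto its internal Hilbert
#' phase in the delta band. The phase is anchored at 0 at the depolarization
#' maximum and spans (up to numerical tolerance) \eqn{[-3\pi/2, \pi/2]} over
#' the wave: \eqn{-3\pi/2} at the initial negative-going zero crossing,
#' \eqn{-\pi} at the hyperpolarization trough, 0 at the depolarization peak
#' and \eqn{+\pi/2} at the final crossing.
#'
#' @slot times sample times in seconds spanning the wave.
#' @slot phases unwrapped phase in radians, non-decreasing along the wave.
#' @slot zeroTime time (s) of the depolarization maximum (phase 0).
#' @slot ok logical; `FALSE` when the unwrapped phase is non-monotone or runs
#'   outside the admissible range beyond tolerance (such waves are excluded
#'   from connectivity).
#'
#' @export
setClass("PhaseMap",
  representation(
    times = "numeric",
    phases = "numeric",
    zeroTime = "numeric",
    ok = "logical"
  )
)

setValidity("PhaseMap", function(object) {
  msg <- character()
  if (length(object@times) != length(object@phases))
    msg <- c(msg, "times and phases must have equal length")
  if (length(object@zeroTime) != 1L)
    msg <- c(msg, "zeroTime must be a single number")
  if (length(msg)) msg else TRUE
})

#' Two-component Gaussian mixture of transition frequencies
#'
#' Fitted mixture model of a transition-frequency sample. For the
#' two-component case the components are ordered by mean: the low-frequency
#' component describes slow switchers, the high-frequency component fast
#' switchers, and `fStar` is the crossing frequency where the two weighted
#' component densities intersect (the classification boundary).
#'
#' @slot weights mixing proportions, sum to 1, ordered with the means.
#' @slot means component means in Hz, increasing.
#' @slot sds component standard deviations in Hz, all positive.
#' @slot fStar crossing frequency in Hz (`NA` unless k = 2).
#' @slot logLik maximized log-likelihood in nats.
#' @slot aicByK named numeric, AIC per candidate component count (filled by
#'   [selectComponents()]; for a direct fit it holds the fitted k only).
#' @slot nObs number of observations fitted.
#' @slot iterations EM iterations used.
#'
#' @export
setClass("SwitcherMixture",
  representation(
    weights = "numeric",
    means = "numeric",
    sds = "numeric",
    fStar = "numeric",
    logLik = "numeric",
    aicByK = "numeric",
    nObs = "integer",
    iterations = "integer"
  )
)

setValidity("SwitcherMixture", function(object) {
  msg <- character()
  k <- length(object@means)
  if (length(object@weights) != k || length(object@sds) != k)
    msg <- c(msg, "weights, means and sds must have equal length")
  if (abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "mixture weights must sum to 1")
  if (any(object@weights <= 0) || any(object@weights >= 1 + 1e-12))
    if (k > 1) msg <- c(msg, "mixture weights must lie in (0, 1)")
  if (is.unsorted(object@means, strictly = FALSE))
    msg <- c(msg, "component means must be sorted increasingly")
  if (any(object@sds <= 0))
    msg <- c(msg, "component standard deviations must be positive")
  if (k == 2 && !is.na(object@fStar)) {
    if (object@fStar <= object@means[1] || object@fStar >= object@means[2])
      msg <- c(msg, "fStar must lie strictly between the component means")
  }
  if (length(msg)) msg else TRUE
})

#' Event-locked phase-lag-index connectivity
#'
#' Connectivity of the EEG montage at fixed phases of the slow-wave
#' depolarization transition. For each phase point it stores the directed
#' phase lag index pli(n*, m) (detection channel n* vs other channel m), the
#' symmetrized PLI matrix, the max-statistics permutation threshold, the
#' significance mask and the global connectivity index (sum of |PLI| over
#' significant pairs).
#'
#' @slot phasePoints named numeric vector of the sampled phases (radians).
#' @slot pliDirected list (one matrix per phase) of directed pli values;
#'   rows = detection channel, columns = other channel; `NA` where the
#'   detection channel had too few events.
#' @slot pliSymmetric list of symmetric PLI matrices with zero diagonal.
#' @slot thresholds numeric vector, per-phase max-statistics threshold on
#'   |PLI| at the stored p-value.
#' @slot significant list of logical matrices marking |PLI| > threshold.
#' @slot gci numeric vector, per-phase global connectivity index.
#' @slot nEvents named numeric, events used per detection channel.
#' @slot nPerm number of permutations used for the null.
#' @slot pValue family-wise significance level of the null.
#'
#' @export
setClass("PhaseConnectivity",
  representation(
    phasePoints = "numeric",
    pliDirected = "list",
    pliSymmetric = "list",
    thresholds = "numeric",
    significant = "list",
    gci = "numeric",
    nEvents = "numeric",
    nPerm = "integer",
    pValue = "numeric"
  )
)

setValidity("PhaseConnectivity", function(object) {
  msg <- character()
  np <- length(object@phasePoints)
  if (length(object@pliSymmetric) != np || length(object@gci) != np ||
      length(object@thresholds) != np || length(object@significant) != np)
    msg <- c(msg, "per-phase slots must have one entry per phase point")
  for (m in object@pliSymmetric) {
    v <- m[is.finite(m)]
    if (length(v) && (max(v) > 1 + 1e-9 || min(v) < -1 - 1e-9))
      msg <- c(msg, "PLI values must lie in [-1, 1]")
    if (any(abs(m - t(m)) > 1e-9, na.rm = TRUE))
      msg <- c(msg, "symmetrized PLI matrices must be symmetric")
  }
  if (any(object@gci < 0))
    msg <- c(msg, "global connectivity index must be non-negative")
  if (length(msg)) unique(msg) else TRUE
})

#' Across-cycle decline of a switcher class
#'
#' Least-squares fit of the per-cycle percentages of one switcher class to an
#' exponential decline: either a decay \eqn{a e^{-rt}} or a reduction
#' \eqn{a - b e^{rt}}, with the cycle index as 1-based time t.
#'
#' @slot form `"decay"` or `"reduction"`.
#' @slot rate unitless exponential rate r per cycle, non-negative.
#' @slot amplitude scale parameter a.
#' @slot offsetScale parameter b of the reduction form (`NA` for decay).
#' @slot rSquared coefficient of determination of the fit.
#' @slot cycles cycle indices the fit used.
#' @slot percentages observed percentages per fitted cycle.
#' @slot fitted model values at the fitted cycles.
#'
#' @export
setClass("DecayFit",
  representation(
    form = "character",
    rate = "numeric",
    amplitude = "numeric",
    offsetScale = "numeric",
    rSquared = "numeric",
    cycles = "numeric",
    percentages = "numeric",
    fitted = "numeric"
  )
)

setValidity("DecayFit", function(object) {
  msg <- character()
  if (!object@form %in% c("decay", "reduction"))
    msg <- c(msg, "form must be 'decay' or 'reduction'")
  if (object@rate < 0)
    msg <- c(msg, "rate must be >= 0")
  if (is.finite(object@rSquared) &&
      (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
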