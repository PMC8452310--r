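# Accessors and show() methods for the S4 containers.

#' Construct an EEGRecording
#'
#' @param signal numeric matrix, channels x samples, microvolts.
#' @param samplingRate sampling rate in Hz.
#' @param channelLabels character vector of channel labels (defaults to the
#'   row names of `signal`).
#' @param reference description of the reference montage.
#' @return an [EEGRecording] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(512), 2, 256), 256, c("Fz", "Cz"))
#' nChannels(rec)
#' @export
EEGRecording <- function(signal, samplingRate,
                         channelLabels = rownames(signal),
                         reference = "linked earlobes") {
  signal <- as.matrix(signal)
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(nrow(signal)))
  rownames(signal) <- channelLabels
  new("EEGRecording", signal = signal, samplingRate = as.numeric(samplingRate),
      channelLabels = as.character(channelLabels),
      reference = as.character(reference))
}

#' @rdname EEGRecording-class
#' @export
setMethod("signalMatrix", "EEGRecording", function(object) object@signal)

#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@samplingRate)

#' @rdname EEGRecording-class
#' @export
setMethod("channelLabels", "EEGRecording",
          function(object) object@channelLabels)

#' @rdname EEGRecording-class
#' @export
setMethod("nChannels", "EEGRecording", function(object) nrow(object@signal))

#' @rdname EEGRecording-class
#' @export
setMethod("nSamples", "EEGRecording", function(object) ncol(object@signal))

#' @rdname EEGRecording-class
#' @export
setMethod("recordingDuration", "EEGRecording",
          function(object) ncol(object@signal) / object@samplingRate)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples (%.1f min at %g Hz)\n",
              nChannels(object), nSamples(object),
              recordingDuration(object) / 60, samplingRate(object)))
  cat("  channels:", paste(channelLabels(object), collapse = " "), "\n")
  cat("  reference:", object@reference, "\n")
})

#' Construct a Hypnogram
#'
#' @param stages character vector of per-epoch stage labels (W/N1/N2/N3/R).
#' @param cycleIndex integer vector of per-epoch sleep-cycle indices
#'   (0 = outside any cycle); defaults to all 0.
#' @param artifact logical vector marking artifact epochs; defaults to none.
#' @param epochLength epoch duration in seconds (30 by convention).
#' @return a [Hypnogram] object.
#' @examples
#' hyp <- Hypnogram(c("W", "N2", "N3", "R"), cycleIndex = c(0, 1, 1, 1))
#' nEpochs(hyp)
#' @export
Hypnogram <- function(stages, cycleIndex = rep(0L, length(stages)),
                      artifact = rep(FALSE, length(stages)),
                      epochLength = 30) {
  new("Hypnogram", stages = as.character(stages),
      cycleIndex = as.integer(cycleIndex),
      artifact = as.logical(artifact),
      epochLength = as.numeric(epochLength))
}

#' @rdname Hypnogram-class
#' @export
setMethod("stages", "Hypnogram", function(object) object@stages)

#' @rdname Hypnogram-class
#' @export
setMethod("cycleIndices", "Hypnogram", function(object) object@cycleIndex)

#' @rdname Hypnogram-class
#' @export
setMethod("artifactMask", "Hypnogram", function(object) object@artifact)

#' @rdname Hypnogram-class
#' @export
setMethod("epochLength", "Hypnogram", function(object) object@epochLength)

#' @rdname Hypnogram-class
#' @export
setMethod("nEpochs", "Hypnogram", function(object) length(object@stages))

setMethod("show", "Hypnogram", function(object) {
  tab <- table(factor(object@stages, levels = c("W", "N1", "N2", "N3", "R")))
  cat(sprintf("Hypnogram: %d epochs of %g s (%.1f min), %d cycle(s)\n",
              nEpochs(object), object@epochLength,
              nEpochs(object) * object@epochLength / 60,
              max(object@cycleIndex)))
  cat("  stages:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      sprintf("| artifact epochs: %d\n", sum(object@artifact)))
})

#' @rdname SwitcherMixture-class
#' @export
setMethod("mixtureWeights", "SwitcherMixture", function(object) object@weights)

#' @rdname SwitcherMixture-class
#' @export
setMethod("mixtureMeans", "SwitcherMixture", function(object) object@means)

#' @rdname SwitcherMixture-class
#' @export
setMethod("mixtureSds", "SwitcherMixture", function(object) object@sds)

#' @rdname SwitcherMixture-class
#' @export
setMethod("fStar", "SwitcherMixture", function(object) object@fStar)

setMethod("show", "SwitcherMixture", function(object) {
  k <- length(object@means)
  cat(sprintf("SwitcherMixture: %d Gaussian component(s), n = %d, logLik = %.2f\n",
              k, object@nObs, object@logLik))
  for (i in seq_len(k))
    cat(sprintf("  component %d: weight %.3f, mean %.3f Hz, sd %.3f Hz\n",
                i, object@weights[i], object@means[i], object@sds[i]))
  if (k == 2 && !is.na(object@fStar))
    cat(sprintf("  crossing frequency f* = %.3f Hz\n", object@fStar))
})

#' @rdname PhaseConnectivity-class
#' @export
setMethod("phasePoints", "PhaseConnectivity",
          function(object) object@phasePoints)

#' @rdname PhaseConnectivity-class
#' @export
setMethod("gci", "PhaseConnectivity", function(object) object@gci)

#' @rdname PhaseConnectivity-class
#' @export
setMethod("pliSymmetric", "PhaseConnectivity",
          function(object) object@pliSymmetric)

#' @rdname PhaseConnectivity-class
#' @export
setMethod("significantPairs", "PhaseConnectivity",
          function(object) object@significant)

setMethod("show", "PhaseConnectivity", function(object) {
  cat(sprintf("PhaseConnectivity: %d phase points, %d permutations, p = %g\n",
              length(object@phasePoints), object@nPerm, object@pValue))
  nsig <- vapply(object@significant,
                 function(m) sum(m[upper.tri(m)], na.rm = TRUE), numeric(1))
  for (i in seq_along(object@phasePoints))
    cat(sprintf("  phase %s (%+.2f rad): threshold %.3f, %d significant pair(s), GCI = %.3f\n",
                names(object@phasePoints)[i], object@phasePoints[i],
                object@thresholds[i], nsig[i], object@gci[i]))
})

#' @rdname DecayFit-class
#' @export
setMethod("decayRate", "DecayFit", function(object) object@rate)

#' @rdname DecayFit-class
#' @export
setMethod("rSquared", "DecayFit", function(object) object@rSquared)

setMethod("show", "DecayFit", function(object) {
  eq <- if (object@form == "decay")
    sprintf("%.3g * exp(-%.3g t)", object@amplitude, object@rate)
  else
    sprintf("%.3g - %.3g * exp(%.3g t)", object@amplitude,
            object@offsetScale, object@rate)
  cat(sprintf("DecayFit (%s): %% = %s, r = %.4g, R^2 = %.4g\n",
              object@form, eq, object@rate, object@rSquared))
})
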