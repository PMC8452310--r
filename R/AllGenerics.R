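#' @rdname EEGRecording-class
#' @param object an object.
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))

#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname EEGRecording-class
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))

#' @rdname EEGRecording-class
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname EEGRecording-class
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname EEGRecording-class
#' @export
setGeneric("recordingDuration",
           function(object) standardGeneric("recordingDuration"))

#' @rdname Hypnogram-class
#' @param object an object.
#' @export
setGeneric("stages", function(object) standardGeneric("stages"))

#' @rdname Hypnogram-class
#' @export
setGeneric("cycleIndices", function(object) standardGeneric("cycleIndices"))

#' @rdname Hypnogram-class
#' @export
setGeneric("artifactMask", function(object) standardGeneric("artifactMask"))

#' @rdname Hypnogram-class
#' @export
setGeneric("epochLength", function(object) standardGeneric("epochLength"))

#' @rdname Hypnogram-class
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @rdname SwitcherMixture-class
#' @param object an object.
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))

#' @rdname SwitcherMixture-class
#' @export
setGeneric("mixtureMeans", function(object) standardGeneric("mixtureMeans"))

#' @rdname SwitcherMixture-class
#' @export
setGeneric("mixtureSds", function(object) standardGeneric("mixtureSds"))

#' @rdname SwitcherMixture-class
#' @export
setGeneric("fStar", function(object) standardGeneric("fStar"))

#' @rdname PhaseConnectivity-class
#' @param object an object.
#' @export
setGeneric("phasePoints", function(object) standardGeneric("phasePoints"))

#' @rdname PhaseConnectivity-class
#' @export
setGeneric("gci", function(object) standardGeneric("gci"))

#' @rdname PhaseConnectivity-class
#' @export
setGeneric("pliSymmetric", function(object) standardGeneric("pliSymmetric"))

#' @rdname PhaseConnectivity-class
#' @export
setGeneric("significantPairs",
           function(object) standardGeneric("significantPairs"))

#' @rdname DecayFit-class
#' @param object an object.
#' @export
setGeneric("decayRate", function(object) standardGeneric("decayRate"))

#' @rdname DecayFit-class
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
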