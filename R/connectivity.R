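# Event-locked phase-lag-index connectivity at fixed slow-wave phases.
#
# For waves detected on channel n*, the directed phase lag index against
# any other channel m is the mean over waves of sign(sin(phi_n* - phi_m)),
# evaluated at the sampled phase point. It is insensitive to zero-lag
# (volume-conducted) synchrony and saturates at +-1 for a constant
# non-vanishing propagation delay. The symmetrized PLI averages the two
# detection directions; significance uses a max-statistics permutation null
# over all electrode pairs.

#' Directed event phase lag index
#'
#' Mean over events of `sign(sin(phiDet - phiOther))`. `phiOther` may be a
#' matrix with one column per channel, giving the directed pli of the
#' detection channel against each column.
#'
#' @param phiDet numeric vector: the detection channel's phase at the
#'   sampled phase point, one value per wave.
#' @param phiOther numeric vector or events-x-channels matrix of the other
#'   channels' simultaneous phases.
#' @return numeric scalar or per-column vector in `[-1, 1]`.
#' @examples
#' eventPli(c(0, 0.5), c(-0.4, 0.1))   # both diffs positive: 1
#' @export
eventPli <- function(phiDet, phiOther) {
  if (is.matrix(phiOther)) colMeans(sign(sin(phiDet - phiOther)))
  else mean(sign(sin(phiDet - phiOther)))
}

#' Symmetrize the two directed pli values of a channel pair
#'
#' `PLI(n, m) = (pli(n*, m) + pli(n, m*)) / 2`; when one direction is
#' unavailable (detection channel dropped for too few events) the available
#' one is used.
#'
#' @param pliA directed pli with n as detection channel.
#' @param pliB directed pli with m as detection channel.
#' @return symmetrized PLI.
#' @export
symmetrizePli <- function(pliA, pliB) {
  out <- (pliA + pliB) / 2
  out[is.na(pliA)] <- pliB[is.na(pliA)]
  out[is.na(pliB)] <- pliA[is.na(pliB)]
  out
}

#' Directed pli matrix of one phase point
#'
#' Builds the full detection-channel-by-other-channel pli matrix from one
#' phase point's event-phase data. `phaseData` is a named list over
#' detection channels; element n is an events-x-channels matrix of phases
#' sampled at the phase point, whose column n holds the detection channel's
#' own phase. Channels absent from the list (too few events) give NA rows.
#'
#' @param phaseData named list of events-x-channels phase matrices.
#' @param channels full channel set for the matrix dimensions.
#' @return M x M matrix of directed pli values, zero diagonal.
#' @export
directedPliMatrix <- function(phaseData, channels = names(phaseData)) {
  M <- length(channels)
  D <- matrix(NA_real_, M, M, dimnames = list(channels, channels))
  for (n in names(phaseData)) {
    mat <- phaseData[[n]]
    if (is.null(mat) || !nrow(mat)) next
    D[n, colnames(mat)] <- eventPli(mat[, n], mat)
  }
  diag(D) <- 0
  D
}

#' Symmetric PLI matrix from the directed matrix
#'
#' Pairs the two detection directions of each channel pair keeping the
#' phase-difference argument order fixed: with `D[n, m]` the mean of
#' `sign(sin(phi_n - phi_m))` over waves detected on n, the second directed
#' value of the pair (waves detected on m, same argument order) is
#' `pli(n, m*) = -D[m, n]`. A true propagation with constant delay gives
#' two reinforcing directed values, while the detection-role swap alone
#' flips the sign of the raw difference. The paired average is mirrored
#' symmetrically (upper-triangle orientation), so `S[n, m] = S[m, n]`.
#'
#' @param D directed pli matrix from [directedPliMatrix()].
#' @return symmetric PLI matrix with zero diagonal; where one direction is
#'   missing the available one is carried through.
#' @export
symmetricPliMatrix <- function(D) {
  A <- symmetrizePli(D, -t(D))
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  dimnames(A) <- dimnames(D)
  A
}

#' Max-statistics resampling threshold for PLI significance
#'
#' For each phase point the non-detection channels' phases are resampled at
#' random (independent uniform phases per event, per channel, per
#' resample), the symmetrized |PLI| matrix is recomputed and its maximum
#' over all electrode pairs recorded; the threshold is the `1 - p` empirical
#' quantile (linear interpolation) of the max distribution, controlling the
#' family-wise error over all pairs. Uniform resampling (rather than
#' permuting event indices) is essential here: a constant inter-channel
#' phase lag -- the very signal PLI detects -- survives any permutation of
#' event indices, so a permutation null would reproduce the effect under
#' test and have no power against it.
#'
#' @param phaseData one phase point's event-phase data: named list over
#'   detection channels of events-x-channels phase matrices.
#' @param nPerm number of permutations.
#' @param p family-wise significance level.
#' @param seed RNG seed (required for reproducibility).
#' @param returnNull also return the permutation max distribution.
#' @return threshold on |PLI| (scalar), or a list with `threshold` and
#'   `nullMax` when `returnNull` is `TRUE`. The threshold is `Inf` when no
#'   detection channel has enough events.
#' @export
nullThreshold <- function(phaseData, nPerm = 1000, p = 0.01, seed,
                          returnNull = FALSE) {
  if (missing(seed)) stop("a seed is required for the permutation null")
  if (nPerm < 100) warning("fewer than 100 permutations gives a coarse threshold")
  channels <- unique(c(names(phaseData),
                       unlist(lapply(phaseData, colnames), use.names = FALSE)))
  M <- length(channels)
  if (M < 2L || !length(phaseData)) {
    thr <- Inf
    return(if (returnNull) list(threshold = thr, nullMax = numeric(0)) else thr)
  }
  D <- array(NA_real_, c(M, M, nPerm),
             dimnames = list(channels, channels, NULL))
  with_seed(seed, {
    for (n in names(phaseData)) {
      mat <- phaseData[[n]]
      if (is.null(mat) || !nrow(mat)) next
      N <- nrow(mat)
      phiDet <- mat[, n]
      for (m in setdiff(colnames(mat), n)) {
        permPhi <- matrix(stats::runif(N * nPerm, -pi, pi), N, nPerm)
        D[n, m, ] <- colMeans(sign(sin(phiDet - permPhi)))
      }
      D[n, n, ] <- 0
    }
  })
  ut <- upper.tri(matrix(0, M, M))
  nullMax <- vapply(seq_len(nPerm), function(pp) {
    S <- symmetrizePli(D[, , pp], -t(D[, , pp]))
    v <- abs(S[ut])
    v <- v[is.finite(v)]
    if (length(v)) max(v) else NA_real_
  }, numeric(1))
  thr <- if (all(is.na(nullMax))) Inf
         else stats::quantile(nullMax, 1 - p, names = FALSE, type = 7,
                              na.rm = TRUE)
  if (returnNull) list(threshold = thr, nullMax = nullMax) else thr
}

#' Global connectivity index
#'
#' Sum of |PLI| over the significant electrode pairs (upper triangle) at
#' one phase point; 0 when no pair is significant.
#'
#' @param pliSym symmetric PLI matrix.
#' @param mask logical matrix marking significant pairs.
#' @return non-negative scalar.
#' @export
globalConnectivityIndex <- function(pliSym, mask) {
  ut <- upper.tri(pliSym)
  sum(abs(pliSym[ut & mask]), na.rm = TRUE)
}

#' Collect event-locked phase data for each phase point
#'
#' For every wave with a valid (monotone, in-range) phase map, inverts the
#' map at the target phases and samples all channels' wrapped instantaneous
#' phase at those times; waves are grouped by detection channel and
#' channels with fewer than `minEvents` usable waves are dropped.
#'
#' @param waves data.frame of detected slow waves.
#' @param wrappedPhase channels-x-samples matrix of wrapped instantaneous
#'   phase of the phase-band signal (row names = channel labels).
#' @param sr sampling rate in Hz.
#' @param phases named numeric vector of target phases.
#' @param minEvents minimum waves per detection channel.
#' @return list (one element per phase point) of named lists of
#'   events-x-channels phase matrices, as consumed by
#'   [directedPliMatrix()] and [nullThreshold()].
#' @export
buildPhaseData <- function(waves, wrappedPhase, sr,
                           phases = c(a = -pi, b = -3 * pi / 4, c = -pi / 2,
                                      d = -pi / 4, e = 0, f = pi / 4),
                           minEvents = 20) {
  channels <- rownames(wrappedPhase)
  nSamp <- ncol(wrappedPhase)
  times <- matrix(NA_real_, nrow(waves), length(phases))
  keep <- logical(nrow(waves))
  for (i in seq_len(nrow(waves))) {
    w <- waves[i, ]
    pm <- .phaseMapFromWrapped(wrappedPhase[w$channel, ], w, sr)
    if (!pm@ok) next
    keep[i] <- TRUE
    times[i, ] <- samplePhasePoints(pm, phases)$time
  }
  out <- lapply(seq_along(phases), function(pi_) {
    dat <- list()
    for (n in channels) {
      sel <- keep & waves$channel == n & is.finite(times[, pi_])
      if (sum(sel) < minEvents) next
      tIdx <- pmin(pmax(round(times[sel, pi_] * sr) + 1L, 1L), nSamp)
      dat[[n]] <- t(wrappedPhase[, tIdx, drop = FALSE])
    }
    dat
  })
  names(out) <- names(phases)
  out
}

#' Event-locked PLI connectivity across slow-wave phases
#'
#' Computes, for each of the six phase points along the depolarization
#' transition, the directed and symmetrized phase-lag-index matrices over
#' the montage, a max-statistics permutation threshold at the given
#' significance level, the significant-pair mask (on |PLI|) and the global
#' connectivity index. Waves are grouped by detection channel; channels
#' with fewer than `minEvents` usable waves are dropped from the directed
#' computation (their phases still serve as "other" channels).
#'
#' @param recording an [EEGRecording] (raw signal; the phase band is
#'   filtered internally) or a channels-x-samples matrix of *phase-band
#'   filtered* signal with `prefiltered = TRUE`.
#' @param waves data.frame of detected slow waves to lock to.
#' @param sr sampling rate (taken from the recording when available).
#' @param phases named vector of target phases in radians.
#' @param band phase band in Hz.
#' @param nPerm permutations for the null threshold.
#' @param p family-wise significance level.
#' @param minEvents minimum waves per detection channel.
#' @param seed RNG seed for the permutation null.
#' @param prefiltered set `TRUE` when `recording` is already band-limited.
#' @return a [PhaseConnectivity] object.
#' @export
phaseConnectivity <- function(recording, waves, sr = NULL,
                              phases = c(a = -pi, b = -3 * pi / 4,
                                         c = -pi / 2, d = -pi / 4,
                                         e = 0, f = pi / 4),
                              band = c(0.16, 4.0), nPerm = 1000, p = 0.01,
                              minEvents = 20, seed, prefiltered = FALSE) {
  if (missing(seed)) stop("a seed is required for the permutation null")
  r <- .resolveSignal(recording, sr)
  filt <- if (prefiltered) r$sig
          else bandpassPhaseBand(r$sig, band[1], band[2], sr = r$sr)
  wrapped <- t(apply(filt, 1L, instantaneousPhase))
  dimnames(wrapped) <- dimnames(r$sig)
  phaseData <- buildPhaseData(waves, wrapped, r$sr, phases, minEvents)
  channels <- rownames(wrapped)
  pliDir <- list(); pliSym <- list(); masks <- list()
  thresholds <- numeric(length(phases))
  gciVals <- numeric(length(phases))
  for (i in seq_along(phases)) {
    D <- directedPliMatrix(phaseData[[i]], channels)
    S <- symmetricPliMatrix(D)
    thr <- nullThreshold(phaseData[[i]], nPerm = nPerm, p = p,
                         seed = splitSeed(seed, i))
    mask <- !is.na(S) & abs(S) > thr
    diag(mask) <- FALSE
    pliDir[[i]] <- D; pliSym[[i]] <- S; masks[[i]] <- mask
    thresholds[i] <- thr
    gciVals[i] <- globalConnectivityIndex(S, mask)
  }
  nEv <- vapply(channels, function(n) {
    m <- phaseData[[1]][[n]]
    if (is.null(m)) 0 else nrow(m)
  }, numeric(1))
  names(pliDir) <- names(pliSym) <- names(masks) <- names(phases)
  new("PhaseConnectivity", phasePoints = phases, pliDirected = pliDir,
      pliSymmetric = pliSym, thresholds = thresholds, significant = masks,
      gci = gciVals, nEvents = nEv, nPerm = as.integer(nPerm), pValue = p)
}
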