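# End-to-end orchestration: detection -> transition metrics -> mixture ->
# labeling -> connectivity -> cycle dynamics, with all tables and model
# files written to an output directory.

#' Pipeline run configuration
#'
#' All detection, mixture, connectivity and cycle parameters in one place.
#' Defaults are the analysis constants: 0.3-4.0 Hz detection band, -40 uV
#' negative peak, 75 uV peak-to-peak, 125-1500 ms negative and <= 1000 ms
#' positive deflection, 10-16 Hz sigma band with the 75th-percentile
#' envelope threshold and 0.5-3 s duration, 0.16-4 Hz phase band,
#' max-statistics p = 0.01, and AIC-based component selection.
#'
#' @param input `"synthetic"` or `"files"`.
#' @param synthetic a [syntheticConfig()] for synthetic input.
#' @param edfPath,hypnogramPath input files for `input = "files"`.
#' @param deltaBand,sigmaBand,phaseBand frequency bands in Hz.
#' @param negPeakMax,p2pMin,negDurRange,posDurMax slow-wave criteria.
#' @param spindlePercentile,spindleDurRange spindle detector parameters.
#' @param kMax largest mixture order tried by AIC.
#' @param connectivity compute PLI connectivity?
#' @param nPerm,pValue,minEvents connectivity null parameters.
#' @param stratifySwitcher compute connectivity separately for slow and
#'   fast switchers (in addition to all waves)?
#' @param fitCycles cycle indices entering the decay fits.
#' @param outDir output directory (created if missing); `NULL` disables
#'   file output.
#' @param seed master seed for generation and permutation nulls.
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(input = c("synthetic", "files"),
                      synthetic = syntheticConfig(),
                      edfPath = NULL, hypnogramPath = NULL,
                      deltaBand = c(0.3, 4.0), sigmaBand = c(10, 16),
                      phaseBand = c(0.16, 4.0),
                      negPeakMax = -40, p2pMin = 75,
                      negDurRange = c(0.125, 1.5), posDurMax = 1.0,
                      spindlePercentile = 0.75, spindleDurRange = c(0.5, 3),
                      kMax = 5, connectivity = TRUE, nPerm = 1000,
                      pValue = 0.01, minEvents = 20,
                      stratifySwitcher = FALSE, fitCycles = 1:3,
                      outDir = NULL, seed = 1) {
  cfg <- as.list(environment())
  cfg$input <- match.arg(input)
  class(cfg) <- "RunConfig"
  cfg
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
}

.mixtureToList <- function(fit) {
  list(weights = fit@weights, means_hz = fit@means, sds_hz = fit@sds,
       f_star_hz = fit@fStar, log_lik = fit@logLik,
       aic_by_k = as.list(fit@aicByK), n_obs = fit@nObs)
}

.connectivityTables <- function(conn) {
  gciTab <- data.frame(phase_label = names(phasePoints(conn)),
                       phase_rad = as.numeric(phasePoints(conn)),
                       threshold = conn@thresholds,
                       n_significant = vapply(conn@significant, function(m)
                         sum(m[upper.tri(m)], na.rm = TRUE), numeric(1)),
                       gci = gci(conn))
  adj <- lapply(names(phasePoints(conn)), function(ph) {
    m <- conn@pliSymmetric[[ph]]
    data.frame(phase_label = ph,
               channel_a = rownames(m)[row(m)[upper.tri(m)]],
               channel_b = colnames(m)[col(m)[upper.tri(m)]],
               pli = m[upper.tri(m)],
               significant = conn@significant[[ph]][upper.tri(m)])
  })
  list(gci = gciTab, edges = do.call(rbind, adj))
}

#' Run the full switcher analysis pipeline
#'
#' Executes detection, transition metrics, mixture fitting and AIC model
#' selection, wave labeling, event-locked connectivity and across-cycle
#' decay fits, writing per-event tables (CSV), model parameters (JSON),
#' connectivity matrices and a run manifest to `outDir`. Identical
#' configuration and seed give identical outputs.
#'
#' @param config a [runConfig()].
#' @return invisible list with `recording`, `hypnogram`, `groundTruth`
#'   (synthetic input only), `waves`, `spindles`, `mixture`, `aicByK`,
#'   `connectivity` (and per-class stratifications when requested),
#'   `cyclePercentages` and `decayFits`.
#' @export
runPipeline <- function(config = runConfig()) {
  cfg <- config
  gt <- NULL
  if (cfg$input == "synthetic") {
    gen <- generateRecording(cfg$synthetic)
    rec <- gen$recording; hyp <- gen$hypnogram; gt <- gen$groundTruth
  } else {
    if (is.null(cfg$edfPath) || is.null(cfg$hypnogramPath))
      stop("file input needs edfPath and hypnogramPath")
    if (!file.exists(cfg$edfPath)) stop("EDF file not found: ", cfg$edfPath)
    if (!file.exists(cfg$hypnogramPath))
      stop("hypnogram file not found: ", cfg$hypnogramPath)
    rec <- readEDF(cfg$edfPath)
    hyp <- readHypnogram(cfg$hypnogramPath)
  }
  sr <- samplingRate(rec)
  message(sprintf("recording: %d channels, %.1f min", nChannels(rec),
                  recordingDuration(rec) / 60))

  delta <- bandpassDelta(rec, cfg$deltaBand[1], cfg$deltaBand[2])
  waves <- detectSlowWaves(delta, hyp, sr, negPeakMax = cfg$negPeakMax,
                           p2pMin = cfg$p2pMin, negDurRange = cfg$negDurRange,
                           posDurMax = cfg$posDurMax)
  message(sprintf("slow waves detected: %d", nrow(waves)))

  sigma <- bandpassSigma(rec, cfg$sigmaBand[1], cfg$sigmaBand[2])
  spindles <- detectSpindles(sigma, hyp, sr, percentile = cfg$spindlePercentile,
                             durRange = cfg$spindleDurRange)
  message(sprintf("spindles detected: %d", nrow(spindles)))

  phaseSig <- bandpassPhaseBand(rec, cfg$phaseBand[1], cfg$phaseBand[2])
  waves <- tagCooccurrence(waves, spindles, phaseSig, sr)
  message(sprintf("waves with co-occurring spindle: %d", sum(waves$has_spindle)))

  mixSeed <- splitSeed(cfg$seed, 11L)
  kSel <- selectComponents(waves$f_tau_hz, kMax = cfg$kMax, seed = mixSeed)
  fit <- fitMixture(waves$f_tau_hz, k = 2, seed = splitSeed(cfg$seed, 12L))
  waves <- classifyWaves(waves, fStar(fit))
  message(sprintf("AIC-selected components: %d; f* = %.3f Hz; p(slow) = %.3f",
                  kSel, fStar(fit), switcherProbability(waves)))

  conn <- NULL
  connStrata <- list()
  if (isTRUE(cfg$connectivity)) {
    conn <- phaseConnectivity(phaseSig, waves, sr = sr, nPerm = cfg$nPerm,
                              p = cfg$pValue, minEvents = cfg$minEvents,
                              seed = splitSeed(cfg$seed, 21L),
                              prefiltered = TRUE)
    if (isTRUE(cfg$stratifySwitcher)) {
      for (cl in c("slow", "fast")) {
        connStrata[[cl]] <- phaseConnectivity(
          phaseSig, waves[waves$switcher == cl, , drop = FALSE], sr = sr,
          nPerm = cfg$nPerm, p = cfg$pValue, minEvents = cfg$minEvents,
          seed = splitSeed(cfg$seed, 22L), prefiltered = TRUE)
      }
    }
  }

  percTab <- cyclePercentages(waves, nCycles = max(cycleIndices(hyp)))
  fitC <- intersect(cfg$fitCycles, unique(percTab$cycle))
  decays <- lapply(c(slow = "slow", fast = "fast"), function(cl) {
    sub <- percTab[percTab$class == cl & percTab$cycle %in% fitC, ]
    if (nrow(sub) >= 3) fitDecay(sub$percentage, sub$cycle) else NULL
  })

  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    outfile <- function(f) file.path(cfg$outDir, f)
    utils::write.csv(waves, outfile("slow_waves.csv"), row.names = FALSE)
    utils::write.csv(spindles, outfile("spindles.csv"), row.names = FALSE)
    .writeJson(c(.mixtureToList(fit),
                 list(aic_selected_k = as.integer(kSel),
                      aic_trace = as.list(attr(kSel, "aicByK")))),
               outfile("mixture.json"))
    utils::write.csv(percTab, outfile("cycle_percentages.csv"),
                     row.names = FALSE)
    .writeJson(lapply(decays, function(d) if (is.null(d)) NULL else
      list(form = d@form, rate = d@rate, r_squared = d@rSquared,
           amplitude = d@amplitude, cycles = d@cycles,
           percentages = d@percentages)), outfile("decay_fits.json"))
    if (!is.null(conn)) {
      tabs <- .connectivityTables(conn)
      utils::write.csv(tabs$gci, outfile("connectivity_gci.csv"),
                       row.names = FALSE)
      utils::write.csv(tabs$edges, outfile("connectivity_edges.csv"),
                       row.names = FALSE)
    }
    manifest <- list(
      package = "switchwave",
      version = as.character(utils::packageVersion("switchwave")),
      seed = cfg$seed,
      input = cfg$input,
      parameters = cfg[setdiff(names(cfg), c("synthetic", "outDir"))],
      synthetic = if (cfg$input == "synthetic") unclass(cfg$synthetic),
      counts = list(slow_waves = nrow(waves), spindles = nrow(spindles),
                    slow_switchers = sum(waves$switcher == "slow"),
                    fast_switchers = sum(waves$switcher == "fast")))
    .writeJson(manifest, outfile("manifest.json"))
  }
  invisible(list(recording = rec, hypnogram = hyp, groundTruth = gt,
                 waves = waves, spindles = spindles, mixture = fit,
                 aicByK = attr(kSel, "aicByK"), kSelected = as.integer(kSel),
                 connectivity = conn, connectivityByClass = connStrata,
                 cyclePercentages = percTab, decayFits = decays))
}
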