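# Minimal EDF (European Data Format) interchange: 16-bit integer records
# with physical units in microvolts, plus plain-text hypnogram and JSON
# ground-truth annotation files.

.padField <- function(x, width) {
  s <- formatC(as.character(x), width = width, flag = "-")
  substr(s, 1L, width)
}

#' Write an EEGRecording to an EDF file
#'
#' Standard EDF: ASCII header plus 16-bit little-endian integer data
#' records of one second each. Physical ranges are set per channel to the
#' symmetric data range, so the quantization step is
#' `2 * max|x| / 65535` microvolts. A trailing partial second is zero-padded.
#'
#' @param recording an [EEGRecording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(recording, path) {
  sig <- signalMatrix(recording)
  sr <- samplingRate(recording)
  if (abs(sr - round(sr)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  sr <- as.integer(round(sr))
  ns <- nrow(sig)
  nRec <- ceiling(ncol(sig) / sr)
  pad <- nRec * sr - ncol(sig)
  if (pad > 0) sig <- cbind(sig, matrix(0, ns, pad))
  physMax <- pmax(apply(abs(sig), 1L, max), 1)
  physMin <- -physMax
  digMax <- 32767L; digMin <- -32768L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.padField(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr(paste("Startdate 01.01.2000 synthetic recording,", recording@reference),
     80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(nRec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (lab in channelLabels(recording)) wr(paste("EEG", lab), 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(physMin[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(format(physMax[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(digMin, 8)
  for (i in seq_len(ns)) wr(digMax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(sr, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nRec)) {
    cols <- ((r - 1L) * sr + 1L):(r * sr)
    for (i in seq_len(ns)) {
      d <- round((sig[i, cols] - physMin[i]) * scale[i]) + digMin
      writeBin(as.integer(pmin(pmax(d, digMin), digMax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into an EEGRecording
#'
#' Reads continuous EDF with a common sampling rate across channels.
#'
#' @param path EDF file path.
#' @return an [EEGRecording].
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80)
  recId <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  labels <- sub("^EEG ", "", labels)
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)          # physical dimension
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("channels with differing sampling rates are not supported")
  sr <- spr[1] / recDur
  sig <- matrix(0, ns, nRec * spr[1])
  for (r in seq_len(nRec)) {
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little")
      sig[i, cols] <- physMin[i] +
        (d - digMin[i]) * (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    }
  }
  reference <- sub("^.*recording,\\s*", "", recId)
  EEGRecording(sig, sr, labels, reference = reference)
}

#' Write a hypnogram to disk
#'
#' `format = "txt"` writes one stage label per 30-s epoch per line;
#' `format = "csv"` writes columns `epoch,stage,cycle,artifact`.
#'
#' @param hypnogram a [Hypnogram].
#' @param path output path.
#' @param format `"txt"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeHypnogram <- function(hypnogram, path, format = c("csv", "txt")) {
  format <- match.arg(format)
  if (format == "txt") {
    writeLines(stages(hypnogram), path)
  } else {
    utils::write.csv(data.frame(epoch = seq_len(nEpochs(hypnogram)),
                                stage = stages(hypnogram),
                                cycle = cycleIndices(hypnogram),
                                artifact = artifactMask(hypnogram)),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a hypnogram from disk
#'
#' Accepts the plain-text (one stage per line) and CSV
#' (`epoch,stage,cycle,artifact`) formats of [writeHypnogram()].
#'
#' @param path file path.
#' @param epochLength epoch duration in seconds.
#' @return a [Hypnogram].
#' @export
readHypnogram <- function(path, epochLength = 30) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    Hypnogram(df$stage, cycleIndex = df$cycle %||% rep(0L, nrow(df)),
              artifact = as.logical(df$artifact %||% rep(FALSE, nrow(df))),
              epochLength = epochLength)
  } else {
    Hypnogram(readLines(path), epochLength = epochLength)
  }
}

#' Write ground-truth annotations as JSON
#'
#' @param groundTruth the `groundTruth` element of [generateRecording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(groundTruth, path) {
  jsonlite::write_json(groundTruth, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read ground-truth annotations from JSON
#'
#' @param path JSON path written by [writeGroundTruth()].
#' @return list with `slowWaveEvents`, `spindleEvents`, `cycleBoundaries`.
#' @export
readGroundTruth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$slowWaveEvents <- as.data.frame(gt$slowWaveEvents)
  gt$spindleEvents <- as.data.frame(gt$spindleEvents)
  gt$cycleBoundaries <- as.data.frame(gt$cycleBoundaries)
  gt
}
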