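# Minimal EDF (European Data Format) reader and writer for continuous
# recordings: fixed 256-byte main header, 256 bytes per signal, 16-bit
# little-endian samples, one-second data records. Covers plain EDF with a
# uniform sampling rate across channels, which is all this pipeline needs.

.padTo <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1L, n)
  formatC(x, width = -n, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Samples are scaled per channel to the full 16-bit digital range; the
#' quantization error is bounded by (physical range)/65534. The sampling
#' rate must be a whole number (one-second data records).
#'
#' @param rec An `EEGRecording` (data in microvolts).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path) {
  fs <- samplingRate(rec)
  if (fs != round(fs)) stopf("writeEDF needs an integer sampling rate")
  x <- signalData(rec)
  ns <- nrow(x)
  nRec <- floor(ncol(x) / fs)
  if (nRec < 1L) stopf("recording shorter than one EDF data record (1 s)")
  x <- x[, seq_len(nRec * fs), drop = FALSE]
  physMin <- apply(x, 1L, min)
  physMax <- apply(x, 1L, max)
  flat <- physMax - physMin < 1e-9
  physMax[flat] <- physMin[flat] + 1
  digMin <- -32767; digMax <- 32767
  scale <- (digMax - digMin) / (physMax - physMin)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .padTo("0", 8),
    .padTo(subjectId(rec), 80),
    .padTo("synthetic recording", 80),
    .padTo("01.01.00", 8), .padTo("00.00.00", 8),
    .padTo(256 * (ns + 1L), 8),
    .padTo("", 44),
    .padTo(nRec, 8),
    .padTo("1", 8),
    .padTo(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, .padTo, character(1), n = width),
                    collapse = ""), con, eos = NULL)
  field(channelNames(rec), 16)
  field(rep("AgAgCl electrode", ns), 80)
  field(rep("uV", ns), 8)
  field(sprintf("%.3f", physMin), 8)
  field(sprintf("%.3f", physMax), 8)
  field(rep(digMin, ns), 8)
  field(rep(digMax, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  for (r in seq_len(nRec)) {
    sel <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      d <- round((x[ch, sel] - physMin[ch]) * scale[ch] + digMin)
      writeBin(as.integer(pmin(pmax(d, digMin), digMax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @return An `EEGRecording` in physical units (microvolts).
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                       # version
  subj <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  rd(80 * ns); rd(8 * ns)
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(32 * ns)
  if (length(unique(spr)) != 1L)
    stopf("mixed per-channel sampling rates are not supported")
  fs <- spr[1L] / recDur
  gain <- (physMax - physMin) / (digMax - digMin)
  x <- matrix(0, ns, nRec * spr[1L])
  for (r in seq_len(nRec)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                   endian = "little")
      x[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        (d - digMin[ch]) * gain[ch] + physMin[ch]
    }
  }
  eegRecording(x, fs, labels, if (nzchar(subj)) subj else "subject")
}
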