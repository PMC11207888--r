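# Preprocessing chain: resampling, mastoid re-referencing, band-pass / notch
# filtering, epoching with margin trimming, baseline correction, and the
# high-frequency power QC gate.

#' Canonical EEG frequency bands
#'
#' Delta, theta, alpha, beta, gamma band edges used throughout the package.
#' The delta band is nominally 0.5-4 Hz, but because the broadband front-end
#' filter high-passes at 1 Hz its effective low edge here is 1 Hz; the
#' nominal edge is kept in the `nominalLow` column.
#'
#' @return data.frame with columns `name`, `low`, `high`, `nominalLow` (Hz).
#' @export
defaultBands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low = c(1, 4, 8, 13, 31),
    high = c(4, 7, 12, 30, 45),
    nominalLow = c(0.5, 4, 8, 13, 31),
    stringsAsFactors = FALSE)
}

#' Continuous multi-channel EEG recording
#'
#' @param data Channels x samples numeric matrix (microvolts).
#' @param samplingRate Sampling rate in Hz.
#' @param channelNames Character vector naming the rows of `data`.
#' @param subjectId Subject identifier.
#' @return An `EEGRecording`.
#' @aliases samplingRate channelNames signalData
#' @export
eegRecording <- function(data, samplingRate, channelNames = rownames(data),
                         subjectId = "subject") {
  if (is.null(channelNames))
    stopf("channel names are required (rownames of data or `channelNames`)")
  rownames(data) <- channelNames
  methods::new("EEGRecording", data = data, samplingRate = samplingRate,
               channelNames = as.character(channelNames),
               subjectId = subjectId)
}

#' @rdname eegRecording
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)

#' @rdname eegRecording
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)

#' @rdname eegRecording
#' @export
setMethod("signalData", "EEGRecording", function(x) x@data)

#' @rdname eegRecording
#' @export
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@samplingRate, ncol(object@data) / object@samplingRate))
})

#' Anti-aliased resampling of a recording
#'
#' Rational-ratio polyphase resampling: zero-stuff upsampling by `p`, FIR
#' anti-aliasing low-pass at the smaller Nyquist frequency, then decimation
#' by `q`, where `targetRate / samplingRate = p / q`. Duration is preserved
#' to within one sample. Only down- or equal-sampling is allowed.
#'
#' @param rec An `EEGRecording`.
#' @param targetRate Requested rate in Hz (must not exceed the current rate).
#' @return Resampled `EEGRecording`.
#' @export
resampleRecording <- function(rec, targetRate) {
  fs <- samplingRate(rec)
  if (targetRate > fs)
    stopf("upsampling (%g -> %g Hz) is not supported", fs, targetRate)
  if (targetRate == fs) return(rec)
  pq <- .rationalRatio(targetRate / fs)
  p <- pq[["p"]]; q <- pq[["q"]]
  x <- signalData(rec)
  n <- ncol(x)
  if (p > 1L) {
    up <- matrix(0, nrow(x), n * p)
    up[, seq(1L, n * p, by = p)] <- x
    x <- up
  }
  fsUp <- fs * p
  cutoff <- min(fs, targetRate) / 2
  h <- .designLowpass(cutoff * 0.95, fsUp, tb = 0.2 * cutoff) * p
  x <- .applyFIR(x, h)
  x <- x[, seq(1L, ncol(x), by = q), drop = FALSE]
  eegRecording(x, targetRate, channelNames(rec), subjectId(rec))
}

#' Mastoid re-referencing
#'
#' Subtracts the sample-wise mean of the reference electrodes from every
#' other channel and drops the reference channels, leaving the network
#' channel space.
#'
#' @param rec An `EEGRecording` containing the reference channels.
#' @param reference Labels of the reference electrodes (default mastoids
#'   `M1`/`M2`; some montages use `TP9`/`TP10`).
#' @return `EEGRecording` without the reference channels.
#' @export
rereference <- function(rec, reference = c("M1", "M2")) {
  miss <- setdiff(reference, channelNames(rec))
  if (length(miss))
    stopf("reference channel(s) missing from recording: %s",
          paste(miss, collapse = ", "))
  x <- signalData(rec)
  refMean <- colMeans(x[reference, , drop = FALSE])
  keep <- setdiff(channelNames(rec), reference)
  out <- sweep(x[keep, , drop = FALSE], 2L, refMean, "-")
  eegRecording(out, samplingRate(rec), keep, subjectId(rec))
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming windowed-sinc band-pass applied with exact delay compensation
#' (zero phase, stop-band attenuation > 40 dB).
#'
#' @param rec `EEGRecording` (a matrix/vector is also accepted).
#' @param low,high Band edges in Hz, `0 < low < high < Nyquist`.
#' @return Filtered object of the same kind.
#' @export
bandpassFilter <- function(rec, low, high) {
  if (methods::is(rec, "EEGRecording")) {
    h <- .designBandpass(low, high, samplingRate(rec))
    return(eegRecording(.applyFIR(signalData(rec), h), samplingRate(rec),
                        channelNames(rec), subjectId(rec)))
  }
  stopf("bandpassFilter expects an EEGRecording; use bandDecompose for epochs")
}

#' Mains notch filter
#'
#' Narrow FIR band-stop centred on the mains frequency (50 Hz default);
#' frequencies 5 Hz away are attenuated by less than 3 dB. Only needed on
#' real recordings; synthetic data carry no mains interference.
#'
#' @param rec An `EEGRecording`.
#' @param freq Mains frequency in Hz.
#' @param halfWidth Half-width of the stop band in Hz.
#' @return Filtered `EEGRecording`.
#' @export
notchFilter <- function(rec, freq = 50, halfWidth = 3) {
  if (freq >= samplingRate(rec) / 2)
    stopf("notch frequency %g Hz is at or above Nyquist", freq)
  h <- .designBandstop(freq - halfWidth, freq + halfWidth, samplingRate(rec))
  eegRecording(.applyFIR(signalData(rec), h), samplingRate(rec),
               channelNames(rec), subjectId(rec))
}

#' Partition a recording into overlapping epochs
#'
#' Windows of `window` seconds start every `step` seconds from the beginning
#' of the recording; any window overlapping the first or last `trim` seconds
#' is excluded (containment rule). With the defaults (300 s windows, 50%
#' overlap, 300 s margins) a 3750 s session yields exactly 20 epochs.
#'
#' @param rec An `EEGRecording`.
#' @param window Epoch length in seconds.
#' @param step Start-to-start spacing in seconds (window/2 = 50% overlap).
#' @param trim Margin excluded at both ends, in seconds.
#' @return An `EpochSet`; `nEpochs()` is always taken from the data, never
#'   assumed.
#' @aliases epochs nEpochs retainedMask subjectId
#' @export
epochRecording <- function(rec, window = 300, step = window / 2,
                           trim = window) {
  fs <- samplingRate(rec)
  dur <- ncol(signalData(rec)) / fs
  minDur <- 2 * trim + window
  if (dur < minDur)
    stopf("recording lasts %.1f s but >= %.1f s is required (2*trim + window)",
          dur, minDur)
  starts <- seq(0, dur - window + 1e-9, by = step)
  starts <- starts[starts >= trim - 1e-9 & starts + window <= dur - trim + 1e-9]
  nw <- round(window * fs)
  x <- signalData(rec)
  eps <- lapply(starts, function(s0) {
    i0 <- round(s0 * fs)
    x[, (i0 + 1L):(i0 + nw), drop = FALSE]
  })
  methods::new("EpochSet", epochs = eps, samplingRate = fs,
               channelNames = channelNames(rec), epochDuration = window,
               step = step, epochIndex = seq_along(eps) - 1L,
               retained = rep(TRUE, length(eps)), band = "broadband",
               subjectId = subjectId(rec))
}

#' @rdname epochRecording
#' @export
setMethod("epochs", "EpochSet", function(x) x@epochs)

#' @rdname epochRecording
#' @export
setMethod("nEpochs", "EpochSet", function(x) length(x@epochs))

#' @rdname epochRecording
#' @export
setMethod("retainedMask", "EpochSet", function(x) x@retained)

#' @rdname epochRecording
#' @export
setMethod("subjectId", "EpochSet", function(x) x@subjectId)

#' @rdname epochRecording
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)

#' @rdname epochRecording
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channelNames)

setMethod("show", "EpochSet", function(object) {
  cat(sprintf(
    "EpochSet '%s' (%s): %d epochs x %d channels x %.0f s @ %g Hz; %d retained\n",
    object@subjectId, object@band, length(object@epochs),
    length(object@channelNames), object@epochDuration, object@samplingRate,
    sum(object@retained)))
})

#' Whole-epoch baseline correction
#'
#' Removes, per epoch and channel, the mean over the entire epoch, so every
#' corrected channel is exactly zero-mean.
#'
#' @param es An `EpochSet`.
#' @return Baseline-corrected `EpochSet`.
#' @export
baselineCorrect <- function(es) {
  es@epochs <- lapply(es@epochs, function(m) m - rowMeans(m))
  es
}

#' High-frequency power QC gate
#'
#' Flags epochs whose mean 20-40 Hz power (periodogram integral, averaged
#' over channels) exceeds the per-recording median by more than
#' `thresholdDb` decibels. The median is the self-contained reference level;
#' flagged epochs are marked in the retained mask, not deleted, so exclusions
#' stay on record.
#'
#' @param es An `EpochSet` (needs >= 3 epochs for a meaningful median).
#' @param bandLow,bandHigh QC band edges in Hz.
#' @param thresholdDb Rejection threshold in dB above the median.
#' @return `EpochSet` with an updated retained mask.
#' @export
qcReject <- function(es, bandLow = 20, bandHigh = 40, thresholdDb = 6) {
  if (length(es@epochs) < 3L)
    stopf("qcReject needs at least 3 epochs to estimate a reference level")
  fs <- es@samplingRate
  pw <- vapply(es@epochs, function(m) {
    n <- ncol(m)
    f <- (seq_len(n) - 1L) / n * fs
    sel <- f >= bandLow & f <= bandHigh
    sp <- Mod(stats::mvfft(t(m)))^2 / n
    mean(colSums(sp[sel, , drop = FALSE]))
  }, numeric(1))
  ratioDb <- 10 * log10(pw / stats::median(pw))
  es@retained <- es@retained & (ratioDb <= thresholdDb)
  es
}

#' Band-limited copies of an epoch set
#'
#' Applies the zero-phase band-pass to every retained epoch, once per band.
#'
#' @param es An `EpochSet`.
#' @param bands Band table as from [defaultBands()].
#' @return Named list of band-filtered `EpochSet`s (retained epochs only).
#' @export
bandDecompose <- function(es, bands = defaultBands()) {
  keep <- which(es@retained)
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (b in seq_len(nrow(bands))) {
    h <- .designBandpass(bands$low[b], bands$high[b], es@samplingRate)
    filt <- lapply(keep, function(i) .applyFIR(es@epochs[[i]], h))
    out[[b]] <- methods::new("EpochSet", epochs = filt,
                             samplingRate = es@samplingRate,
                             channelNames = es@channelNames,
                             epochDuration = es@epochDuration, step = es@step,
                             epochIndex = es@epochIndex[keep],
                             retained = rep(TRUE, length(keep)),
                             band = bands$name[b], subjectId = es@subjectId)
  }
  out
}

#' Standard preprocessing chain for a raw recording
#'
#' Convenience wrapper reproducing the full front-end: resample to
#' `targetRate`, mastoid re-reference, broadband FIR band-pass, optional
#' mains notch, epoching, whole-epoch baseline correction and the 6 dB
#' high-frequency QC gate. Input is assumed already cleaned of ocular
#' artifacts (no ICA step is provided).
#'
#' @param rec Raw `EEGRecording` including reference channels.
#' @param targetRate Analysis sampling rate (Hz).
#' @param broadband Length-2 band edges of the front-end filter (Hz).
#' @param notch Mains frequency to notch out, or `NULL` to skip (synthetic
#'   data path).
#' @param reference Reference electrode labels.
#' @param window,step,trim Epoching grid in seconds, see [epochRecording()].
#' @param qcThresholdDb QC gate threshold in dB.
#' @return A quality-controlled, baseline-corrected broadband `EpochSet`.
#' @export
preprocessRecording <- function(rec, targetRate = 256, broadband = c(1, 45),
                                notch = 50, reference = c("M1", "M2"),
                                window = 300, step = window / 2, trim = window,
                                qcThresholdDb = 6) {
  rec <- resampleRecording(rec, targetRate)
  rec <- rereference(rec, reference)
  rec <- bandpassFilter(rec, broadband[1], broadband[2])
  if (!is.null(notch)) rec <- notchFilter(rec, notch)
  es <- epochRecording(rec, window = window, step = step, trim = trim)
  es <- baselineCorrect(es)
  qcReject(es, thresholdDb = qcThresholdDb)
}
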