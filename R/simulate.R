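# Synthetic EEG generator. Emulates the study conditions — 21 subjects, 62
# analysis channels, 20 five-minute epochs at 256 Hz — with pink-noise
# background, a zero-lag common source standing in for volume conduction,
# and planted band-limited couplings at non-zero phase lag whose strength
# drifts linearly across epochs (the fatigue surrogate).
#
# Coupling mechanism: for a planted edge (a, b) in band B with coupling
# kappa(e) = base + slope * e at epoch e, channel b receives
#   kappa(e) * (a's band component phase-shifted by phaseLag)
#     + sqrt(1 - kappa(e)^2) * independent band noise,
# a phase-shift-and-mix construction that directly controls the
# phase-difference distribution PLI measures. The zero-lag common source
# inflates amplitude correlation but, by design, not PLI.

#' Simulation configuration
#'
#' Bundles the study-design parameters of the synthetic EEG generator.
#' Defaults mirror the emulated experiment: 21 subjects, 62-channel montage,
#' 20 epochs of 300 s at 256 Hz. `plantedEdges` defaults to none (a pure
#' noise/null dataset); effectful configurations list their couplings
#' explicitly (see [samplePlantedEdges()]).
#'
#' @param nSubjects Number of subjects.
#' @param montage `EEGMontage`; only its network channels are simulated in
#'   epoch mode (the continuous mode adds the reference electrodes).
#' @param samplingRate Sampling rate in Hz (>= twice the highest band edge).
#' @param nEpochs Number of analysis epochs (>= 3).
#' @param epochDuration Epoch length in seconds.
#' @param plantedEdges data.frame with columns `chanA`, `chanB`, `band`,
#'   `phaseLag` (radians, strictly inside (0, pi)), `baseCoupling`,
#'   `couplingSlope` (per epoch step), and optionally a list-column
#'   `subjects` restricting an edge to a subset of subjects (NULL = all).
#' @param noiseSd Standard deviation of the per-channel pink background.
#' @param commonSourceGain Gain of the shared zero-lag broadband source.
#' @param edgeAmplitude Amplitude of planted band components.
#' @param masterSeed Master seed; all randomness derives deterministically
#'   from (masterSeed, subject, epoch), so any epoch is reproducible in
#'   isolation.
#' @param bands Band table, see [defaultBands()].
#' @return A validated `SimConfig`.
#' @export
simConfig <- function(nSubjects = 21, montage = makeDefaultMontage(),
                      samplingRate = 256, nEpochs = 20, epochDuration = 300,
                      plantedEdges = emptyPlantedEdges(), noiseSd = 1,
                      commonSourceGain = 0.4, edgeAmplitude = 1,
                      masterSeed = 1, bands = defaultBands()) {
  methods::new("SimConfig", nSubjects = as.integer(nSubjects),
               montage = montage, samplingRate = samplingRate,
               nEpochs = as.integer(nEpochs), epochDuration = epochDuration,
               plantedEdges = plantedEdges, noiseSd = noiseSd,
               commonSourceGain = commonSourceGain,
               edgeAmplitude = edgeAmplitude,
               masterSeed = as.integer(masterSeed), bands = bands)
}

#' @rdname simConfig
#' @export
emptyPlantedEdges <- function() {
  data.frame(chanA = character(), chanB = character(), band = character(),
             phaseLag = numeric(), baseCoupling = numeric(),
             couplingSlope = numeric(), stringsAsFactors = FALSE)
}

#' Sample a set of planted edges for one band
#'
#' Draws `n` channel pairs with disjoint endpoints (so planted couplings do
#' not interact within a band), random phase lags well inside (0, pi), and
#' the requested coupling ramps. A list of subject subsets can restrict each
#' edge to part of the cohort.
#'
#' @param montage `EEGMontage` supplying the channel labels.
#' @param band Band name.
#' @param n Number of edges.
#' @param baseCoupling,couplingSlope Vectors (recycled to `n`) defining the
#'   coupling ramp kappa(e) = base + slope * e.
#' @param phaseLagRange Range the phase lags are drawn from.
#' @param subjects Optional list of integer vectors (or NULLs), one per edge.
#' @return data.frame suitable for `simConfig(plantedEdges = ...)`. Uses the
#'   current RNG state; seed it for reproducibility.
#' @export
samplePlantedEdges <- function(montage, band, n, baseCoupling, couplingSlope,
                               phaseLagRange = c(pi / 4, 3 * pi / 4),
                               subjects = NULL) {
  labs <- montageLabels(montage)
  if (2 * n > length(labs))
    stopf("cannot place %d disjoint edges on %d channels", n, length(labs))
  picked <- sample(labs, 2 * n)
  a <- picked[seq_len(n)]
  b <- picked[n + seq_len(n)]
  swap <- match(a, labs) > match(b, labs)  # keep montage (upper-tri) order
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(chanA = a, chanB = b, band = band,
                    phaseLag = stats::runif(n, phaseLagRange[1],
                                            phaseLagRange[2]),
                    baseCoupling = rep_len(baseCoupling, n),
                    couplingSlope = rep_len(couplingSlope, n),
                    stringsAsFactors = FALSE)
  if (!is.null(subjects)) out$subjects <- I(rep_len(subjects, n))
  out
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d subjects, %d epochs x %.0f s @ %g Hz, %d channels\n",
    object@nSubjects, object@nEpochs, object@epochDuration,
    object@samplingRate, length(montageLabels(object@montage))))
  cat(sprintf("  planted edges: %d | noiseSd %.2f | commonSourceGain %.2f | seed %d\n",
              nrow(object@plantedEdges), object@noiseSd,
              object@commonSourceGain, object@masterSeed))
})

# 1/f ("pink") noise, one row per channel, unit sd per channel scaled to sd.
.pinkNoise <- function(nch, n, fs, sd) {
  if (sd == 0) return(matrix(0, nch, n))
  W <- stats::mvfft(matrix(stats::rnorm(nch * n), n, nch))
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  amp <- 1 / sqrt(pmax(f, fs / n))          # 1/f power, DC floored
  amp[1L] <- 0
  X <- Re(stats::mvfft(W * amp, inverse = TRUE)) / n
  X <- t(X)
  X * (sd / apply(X, 1L, stats::sd))
}

# Unit-sd band-limited Gaussian noise (one series).
.bandNoise <- function(n, h) {
  x <- .applyFIR(stats::rnorm(n), h)
  x / stats::sd(x)
}

# Shift the instantaneous phase of a narrow-band series by -lag, so the
# original leads the copy by `lag` radians.
.phaseShift <- function(x, lag) {
  Re(drop(.analyticMatrix(matrix(x, 1L))) * exp(-1i * lag))
}

.activeFor <- function(pe, subjectIndex) {
  if (is.null(pe$subjects)) return(rep(TRUE, nrow(pe)))
  vapply(pe$subjects, function(s) is.null(s) || subjectIndex %in% s,
         logical(1))
}

#' Simulate one analysis epoch
#'
#' Generates the channels x samples matrix for one subject and epoch:
#' per-channel pink background, the shared zero-lag source, and every
#' planted coupling at its epoch-`e` strength. Identical
#' (config, subject, epoch) triples give bit-identical output.
#'
#' @param config A `SimConfig`.
#' @param subjectIndex Subject number in `1:nSubjects`.
#' @param epochIndex Epoch number in `0:(nEpochs - 1)`.
#' @return Numeric matrix (network channels x samples), rownames = labels.
#' @export
simulateEpoch <- function(config, subjectIndex, epochIndex) {
  if (epochIndex < 0L || epochIndex >= config@nEpochs)
    stopf("epochIndex %d outside 0..%d", epochIndex, config@nEpochs - 1L)
  if (subjectIndex < 1L || subjectIndex > config@nSubjects)
    stopf("subjectIndex %d outside 1..%d", subjectIndex, config@nSubjects)
  labs <- montageLabels(config@montage)
  fs <- config@samplingRate
  n <- round(config@epochDuration * fs)
  withr_seed <- seedFor(config@masterSeed, subjectIndex, epochIndex)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)

  x <- .pinkNoise(length(labs), n, fs, config@noiseSd)
  rownames(x) <- labs
  if (config@commonSourceGain > 0) {
    common <- .pinkNoise(1L, n, fs, 1)[1L, ]
    x <- x + rep(config@commonSourceGain, length(labs)) %o% common
  }
  pe <- config@plantedEdges
  if (nrow(pe)) {
    active <- .activeFor(pe, subjectIndex)
    for (bn in unique(pe$band)) {
      brow <- config@bands[config@bands$name == bn, ]
      h <- .designBandpass(brow$low, brow$high, fs)
      for (i in which(pe$band == bn)) {
        if (!active[i]) next
        src <- .bandNoise(n, h)
        nb <- .bandNoise(n, h)
        k <- pe$baseCoupling[i] + pe$couplingSlope[i] * epochIndex
        comp <- k * .phaseShift(src, pe$phaseLag[i]) + sqrt(1 - k^2) * nb
        x[pe$chanA[i], ] <- x[pe$chanA[i], ] + config@edgeAmplitude * src
        x[pe$chanB[i], ] <- x[pe$chanB[i], ] + config@edgeAmplitude * comp
      }
    }
  }
  x
}

#' Simulate a subject's full session on the analysis grid
#'
#' @param config A `SimConfig`.
#' @param subjectIndex Subject number.
#' @return An `EpochSet` of `nEpochs` broadband epochs (all retained).
#' @export
simulateSubject <- function(config, subjectIndex) {
  eps <- lapply(seq_len(config@nEpochs) - 1L,
                function(e) simulateEpoch(config, subjectIndex, e))
  methods::new("EpochSet", epochs = eps, samplingRate = config@samplingRate,
               channelNames = montageLabels(config@montage),
               epochDuration = config@epochDuration,
               step = config@epochDuration / 2,
               epochIndex = seq_len(config@nEpochs) - 1L,
               retained = rep(TRUE, config@nEpochs), band = "broadband",
               subjectId = sprintf("S%02d", subjectIndex))
}

#' @rdname simulateSubject
#' @return `simulateDataset`: list of `EpochSet`, one per subject.
#' @export
simulateDataset <- function(config) {
  lapply(seq_len(config@nSubjects), function(s) simulateSubject(config, s))
}

#' Simulate a continuous recording (for end-to-end epoching tests)
#'
#' Emits one uncut multi-channel recording whose planted coupling strengths
#' ramp linearly between the centres of the first and last analysis windows.
#' Reference electrodes are included as attenuated pink noise so the
#' re-referencing step is exercised. The default duration
#' `2*trim + window + (nEpochs-1)*step` makes the containment epoching rule
#' recover exactly `nEpochs` windows.
#'
#' @param config A `SimConfig`.
#' @param subjectIndex Subject number.
#' @param window,step,trim Epoch grid in seconds the recording is designed
#'   for (defaults: `epochDuration`, 50% overlap, one-window margins).
#' @return An `EEGRecording` with network plus reference channels.
#' @export
simulateContinuous <- function(config, subjectIndex,
                               window = config@epochDuration,
                               step = window / 2, trim = window) {
  labs <- montageLabels(config@montage)
  refs <- referenceLabels(config@montage)
  fs <- config@samplingRate
  dur <- 2 * trim + window + (config@nEpochs - 1L) * step
  n <- round(dur * fs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seedFor(config@masterSeed, subjectIndex, stream = 1L))

  x <- .pinkNoise(length(labs) + length(refs), n, fs, config@noiseSd)
  x[seq_along(refs) + length(labs), ] <- 0.2 *
    x[seq_along(refs) + length(labs), , drop = FALSE]
  rownames(x) <- c(labs, refs)
  if (config@commonSourceGain > 0) {
    common <- .pinkNoise(1L, n, fs, 1)[1L, ]
    x[seq_along(labs), ] <- x[seq_along(labs), ] +
      rep(config@commonSourceGain, length(labs)) %o% common
  }
  pe <- config@plantedEdges
  if (nrow(pe)) {
    tSec <- (seq_len(n) - 1L) / fs
    c0 <- trim + window / 2
    c1 <- trim + (config@nEpochs - 1L) * step + window / 2
    frac <- pmin(pmax((tSec - c0) / (c1 - c0), 0), 1)
    active <- .activeFor(pe, subjectIndex)
    for (bn in unique(pe$band)) {
      brow <- config@bands[config@bands$name == bn, ]
      h <- .designBandpass(brow$low, brow$high, fs)
      for (i in which(pe$band == bn)) {
        if (!active[i]) next
        src <- .bandNoise(n, h)
        nb <- .bandNoise(n, h)
        kEnd <- pe$baseCoupling[i] + pe$couplingSlope[i] * (config@nEpochs - 1L)
        k <- pe$baseCoupling[i] + (kEnd - pe$baseCoupling[i]) * frac
        comp <- k * .phaseShift(src, pe$phaseLag[i]) + sqrt(1 - k^2) * nb
        x[pe$chanA[i], ] <- x[pe$chanA[i], ] + config@edgeAmplitude * src
        x[pe$chanB[i], ] <- x[pe$chanB[i], ] + config@edgeAmplitude * comp
      }
    }
  }
  eegRecording(x, fs, c(labs, refs), sprintf("S%02d", subjectIndex))
}

#' Ground truth of the planted couplings
#'
#' The oracle used by recovery tests (never by the analysis pipeline):
#' planted edges with the sign of their coupling slope and their subject
#' coverage.
#'
#' @param config A `SimConfig`.
#' @return data.frame with `band`, `chanA`, `chanB`, `slopeSign`,
#'   `nSubjects` (carrying the edge) and `coverage` fraction.
#' @export
groundTruth <- function(config) {
  pe <- config@plantedEdges
  if (!nrow(pe)) {
    return(data.frame(band = character(), chanA = character(),
                      chanB = character(), slopeSign = numeric(),
                      nSubjects = integer(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  ns <- if (is.null(pe$subjects)) rep(config@nSubjects, nrow(pe)) else
    vapply(pe$subjects, function(s)
      if (is.null(s)) config@nSubjects else length(unique(s)), integer(1))
  data.frame(band = pe$band, chanA = pe$chanA, chanB = pe$chanB,
             slopeSign = sign(pe$couplingSlope), nSubjects = as.integer(ns),
             coverage = ns / config@nSubjects, stringsAsFactors = FALSE)
}

#' Phase-scrambled surrogate of a series
#'
#' Randomizes the Fourier phases while preserving the amplitude spectrum —
#' the classical null for phase-coupling statistics. Uses the current RNG
#' state.
#'
#' @param x Numeric series.
#' @return Surrogate series of the same length and spectrum.
#' @export
phaseScramble <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  half <- seq(2L, ceiling((n + 1L) / 2L))
  ph <- stats::runif(length(half), -pi, pi)
  X[half] <- Mod(X[half]) * exp(1i * ph)
  mirror <- n + 2L - half
  keep <- mirror != half & mirror <= n
  X[mirror[keep]] <- Conj(X[half][keep])
  Re(stats::fft(X, inverse = TRUE)) / n
}
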