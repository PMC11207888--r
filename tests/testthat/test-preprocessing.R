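sine <- function(f, fs, dur, phase = 0) {
  sin(2 * pi * f * seq(0, dur - 1 / fs, by = 1 / fs) + phase)
}

rms <- function(x) sqrt(mean(x^2))

# attenuation of a pure tone through a recording-level filter, interior only
toneAttenuationDb <- function(filterFun, f, fs, dur = 8) {
  x <- sine(f, fs, dur)
  rec <- eegRecording(matrix(x, 1), fs, "Cz")
  y <- signalData(filterFun(rec))[1, ]
  interior <- seq(round(fs), length(x) - round(fs))
  -20 * log10(rms(y[interior]) / rms(x[interior]))
}

test_that("resampling halves the grid and preserves duration and tones", {
  fs <- 512
  rec <- eegRecording(matrix(rnorm(2 * fs * 60), 2), fs, c("C3", "C4"))
  out <- resampleRecording(rec, 256)
  expect_identical(ncol(signalData(out)), 15360L)   # 60 s * 256 Hz
  expect_identical(samplingRate(out), 256)
  expect_identical(resampleRecording(rec, 512), rec)
  expect_error(resampleRecording(rec, 1024), "upsampling")

  x <- sine(10, 512, 10)
  r10 <- resampleRecording(eegRecording(matrix(x, 1), 512, "Cz"), 256)
  ref <- sine(10, 256, 10)
  interior <- 257:(256 * 9)
  expect_lt(abs(rms(signalData(r10)[1, interior]) / rms(ref[interior]) - 1),
            0.01)
})

test_that("mastoid re-referencing subtracts the reference mean and drops it", {
  labs <- c("C3", "C4", "M1", "M2")
  x <- matrix(rnorm(4 * 100), 4, dimnames = list(labs, NULL))
  rec <- eegRecording(x, 100, labs)
  out <- rereference(rec)
  expect_identical(channelNames(out), c("C3", "C4"))
  refMean <- (x["M1", ] + x["M2", ]) / 2
  expect_equal(signalData(out)["C3", ], x["C3", ] - refMean)
  expect_equal(signalData(out)["C4", ], x["C4", ] - refMean)

  # zero mastoids: network channels unchanged
  x0 <- x; x0[c("M1", "M2"), ] <- 0
  out0 <- rereference(eegRecording(x0, 100, labs))
  expect_equal(signalData(out0), x0[c("C3", "C4"), ])

  # all channels equal to the mastoid mean: output all-zero
  xc <- matrix(rep(rnorm(100), each = 4), 4, dimnames = list(labs, NULL))
  expect_equal(max(abs(signalData(rereference(eegRecording(xc, 100, labs))))),
               0)

  expect_error(rereference(out), "missing")  # no reference left to subtract
})

test_that("band-pass filter has the specified pass/stop behaviour", {
  broadband <- function(rec) bandpassFilter(rec, 1, 45)
  alpha <- function(rec) bandpassFilter(rec, 8, 12)
  expect_gt(toneAttenuationDb(broadband, 0.1, 256, dur = 40), 20)
  expect_gt(toneAttenuationDb(broadband, 50, 256), 20)
  expect_lt(abs(toneAttenuationDb(alpha, 10, 256)), 1)
  expect_gt(toneAttenuationDb(alpha, 20, 256), 40)
  rec <- eegRecording(matrix(rnorm(256), 1), 256, "Cz")
  expect_error(bandpassFilter(rec, 40, 200), "Nyquist")
})

test_that("filtering is zero-phase for in-band components", {
  fs <- 256
  x <- sine(10, fs, 4)
  rec <- eegRecording(matrix(x, 1), fs, "Cz")
  y <- signalData(bandpassFilter(rec, 8, 12))[1, ]
  interior <- (fs + 1):(3 * fs)
  cc <- sapply(-5:5, function(lag)
    sum(x[interior] * y[interior + lag]))
  expect_identical((-5:5)[which.max(cc)], 0L)
})

test_that("notch removes mains but spares the neighbourhood", {
  notch <- function(rec) notchFilter(rec, 50)
  expect_gt(toneAttenuationDb(notch, 50, 256), 20)
  expect_lt(toneAttenuationDb(notch, 45, 256), 3)
  expect_lt(toneAttenuationDb(notch, 55, 256), 3)
})

test_that("epoching follows the containment rule", {
  fs <- 64
  rec <- eegRecording(matrix(rnorm(fs * 3750), 1), fs, "Cz")
  es <- epochRecording(rec)  # 300 s windows, 150 s step, 300 s trim
  expect_identical(nEpochs(es), 20L)

  rec600 <- eegRecording(matrix(seq_len(fs * 600), 1), fs, "Cz")
  es3 <- epochRecording(rec600, window = 300, step = 150, trim = 0)
  expect_identical(nEpochs(es3), 3L)
  # starts at 0, 150, 300 s
  expect_equal(unname(epochs(es3)[[2]][1, 1]), fs * 150 + 1)

  expect_error(epochRecording(rec600, window = 300, step = 150, trim = 300),
               "required")
})

test_that("trim-free non-overlapping epoching partitions the recording", {
  fs <- 32
  x <- matrix(rnorm(2 * fs * 40), 2, dimnames = list(c("C3", "C4"), NULL))
  es <- epochRecording(eegRecording(x, fs, c("C3", "C4")),
                       window = 10, step = 10, trim = 0)
  expect_identical(nEpochs(es), 4L)
  expect_equal(do.call(cbind, epochs(es)), x, ignore_attr = TRUE)
})

test_that("continuous simulation round-trips through the epoching grid", {
  cfg <- simConfig(nSubjects = 1, montage = toyMontage(4), samplingRate = 128,
                   nEpochs = 4, epochDuration = 8, masterSeed = 5)
  rec <- simulateContinuous(cfg, 1)
  expect_identical(ncol(signalData(rec)), 128L * (2L * 8L + 8L + 3L * 4L))
  net <- rereference(rec)
  es <- epochRecording(net, window = 8, step = 4, trim = 8)
  expect_identical(nEpochs(es), cfg@nEpochs)
})

test_that("baseline correction zeroes every channel mean", {
  fs <- 64
  ep1 <- rbind(rep(3, fs), sine(5, fs, 1) + 2)
  es <- makeEpochSet(list(ep1), fs, c("C3", "C4"))
  out <- baselineCorrect(es)
  expect_equal(epochs(out)[[1]][1, ], rep(0, fs))
  expect_equal(epochs(out)[[1]][2, ], sine(5, fs, 1), tolerance = 1e-10)
  expect_lt(max(abs(rowMeans(epochs(out)[[1]]))), 1e-10)
  # already zero-mean channels are unchanged
  z <- matrix(sine(4, fs, 1), 1)
  es2 <- makeEpochSet(list(z, z, z), fs, "Cz")
  expect_equal(epochs(baselineCorrect(es2)), epochs(es2))
})

test_that("QC gate flags epochs with excess 20-40 Hz power", {
  fs <- 128
  base <- function() rbind(sine(30, fs, 2) * 0.5, sine(5, fs, 2))
  eps <- lapply(1:5, function(i) base())
  es <- makeEpochSet(eps, fs, c("C3", "C4"))
  expect_true(all(retainedMask(qcReject(es))))       # identical epochs

  hot <- eps
  hot[[3]] <- rbind(sine(30, fs, 2) * 0.5 * sqrt(10), sine(5, fs, 2))
  esHot <- makeEpochSet(hot, fs, c("C3", "C4"))
  expect_identical(which(!retainedMask(qcReject(esHot))), 3L)
  expect_true(all(retainedMask(qcReject(esHot, thresholdDb = Inf))))

  # monotone: a higher threshold never rejects more
  r6 <- retainedMask(qcReject(esHot, thresholdDb = 6))
  r12 <- retainedMask(qcReject(esHot, thresholdDb = 12))
  expect_true(all(r12 >= r6))
  expect_error(qcReject(makeEpochSet(eps[1:2], fs, c("C3", "C4"))), "3 epochs")
})

test_that("band decomposition emits one filtered copy per band", {
  fs <- 128
  eps <- lapply(1:3, function(i)
    matrix(rnorm(2 * fs * 2), 2, dimnames = list(c("C3", "C4"), NULL)))
  es <- makeEpochSet(eps, fs, c("C3", "C4"))
  es@retained[2] <- FALSE
  bd <- bandDecompose(es, defaultBands()[2:3, ])
  expect_identical(names(bd), c("theta", "alpha"))
  expect_identical(nEpochs(bd$alpha), 2L)            # dropped epoch excluded
  expect_identical(bd$alpha@epochIndex, c(0L, 2L))   # grid preserved
})
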