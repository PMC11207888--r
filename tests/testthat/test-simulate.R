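# The generator's contracts: deterministic seeding, planted couplings that
# PLI can see, and null channels that it cannot.

smallSimConfig <- function(..., montage = toyMontage(4), samplingRate = 128,
                           nEpochs = 3, epochDuration = 8, masterSeed = 3) {
  simConfig(nSubjects = 2, montage = montage, samplingRate = samplingRate,
            nEpochs = nEpochs, epochDuration = epochDuration,
            masterSeed = masterSeed, ...)
}

# Single-epoch PLI of one edge after band filtering.
edgePLIOnce <- function(cfg, band, chanA, chanB, subject = 1, epoch = 0) {
  ep <- simulateEpoch(cfg, subject, epoch)
  es <- makeEpochSet(list(ep), cfg@samplingRate, rownames(ep))
  st <- computeStacks(es, defaultBands()[defaultBands()$name == band, ,
                                         drop = FALSE])
  pliWeights(st[[band]])[fatiguePLI:::edgeKey(chanA, chanB), 1]
}

test_that("identical (config, subject, epoch) triples are bit-identical", {
  cfg <- smallSimConfig()
  expect_identical(simulateEpoch(cfg, 1, 1), simulateEpoch(cfg, 1, 1))
  expect_false(identical(simulateEpoch(cfg, 1, 1), simulateEpoch(cfg, 2, 1)))
  expect_false(identical(simulateEpoch(cfg, 1, 1), simulateEpoch(cfg, 1, 2)))
})

test_that("configuration invariants are enforced", {
  bad <- data.frame(chanA = "F3", chanB = "F4", band = "alpha",
                    phaseLag = pi / 2, baseCoupling = 0.8,
                    couplingSlope = 0.2)
  expect_error(smallSimConfig(plantedEdges = bad), "within \\[0, 1\\]")
  bad$couplingSlope <- 0
  bad$phaseLag <- 0
  expect_error(smallSimConfig(plantedEdges = bad), "inside \\(0, pi\\)")
  bad$phaseLag <- pi
  expect_error(smallSimConfig(plantedEdges = bad), "inside \\(0, pi\\)")
  bad$phaseLag <- pi / 2
  bad$chanB <- "F3"
  expect_error(smallSimConfig(plantedEdges = bad), "distinct")
  expect_error(smallSimConfig(nEpochs = 2), "nEpochs")
  expect_error(smallSimConfig(samplingRate = 60), "Nyquist")
})

test_that("PLI of a planted edge grows monotonically with the coupling", {
  means <- sapply(c(0.2, 0.5, 0.9), function(k) {
    pe <- data.frame(chanA = "F3", chanB = "F4", band = "alpha",
                     phaseLag = pi / 2, baseCoupling = k, couplingSlope = 0)
    mean(sapply(1:10, function(seed) {
      cfg <- smallSimConfig(plantedEdges = pe, masterSeed = seed)
      edgePLIOnce(cfg, "alpha", "F3", "F4")
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("null channel pairs stay below the phase-scrambled 95th percentile", {
  cfg <- smallSimConfig(commonSourceGain = 0)
  obs <- mean(sapply(1:10, function(seed) {
    edgePLIOnce(smallSimConfig(commonSourceGain = 0, masterSeed = seed),
                "alpha", "C3", "C4")
  }))
  # null distribution: scramble one channel's phases, same estimator
  ep <- simulateEpoch(cfg, 1, 0)
  band <- defaultBands()[defaultBands()$name == "alpha", , drop = FALSE]
  es <- makeEpochSet(list(ep), cfg@samplingRate, rownames(ep))
  st <- computeStacks(es, band)
  h <- fatiguePLI:::.designBandpass(band$low, band$high, cfg@samplingRate)
  a <- fatiguePLI:::.applyFIR(ep["C3", ], h)
  b <- fatiguePLI:::.applyFIR(ep["C4", ], h)
  set.seed(99)
  null <- replicate(200, {
    bs <- phaseScramble(b)
    pli(phaseDifference(analyticSignal(a), analyticSignal(bs)))
  })
  expect_lt(obs, quantile(null, 0.95))
})

test_that("subject-restricted edges leave other subjects' data untouched", {
  pe <- data.frame(chanA = "F3", chanB = "F4", band = "alpha",
                   phaseLag = pi / 2, baseCoupling = 0.7, couplingSlope = 0)
  pe$subjects <- I(list(1L))
  withEdge <- smallSimConfig(plantedEdges = pe)
  without <- smallSimConfig()
  expect_identical(simulateEpoch(withEdge, 2, 0), simulateEpoch(without, 2, 0))
  expect_false(identical(simulateEpoch(withEdge, 1, 0),
                         simulateEpoch(without, 1, 0)))
})

test_that("ground truth reports planted edges, signs and coverage", {
  pe <- data.frame(chanA = c("F3", "C3"), chanB = c("F4", "C4"),
                   band = "alpha", phaseLag = pi / 2,
                   baseCoupling = c(0.3, 0.7),
                   couplingSlope = c(0.1, -0.1))
  pe$subjects <- I(list(NULL, 1L))
  cfg <- smallSimConfig(plantedEdges = pe, nEpochs = 4)
  gt <- groundTruth(cfg)
  expect_identical(gt$slopeSign, c(1, -1))
  expect_identical(gt$nSubjects, c(2L, 1L))
  expect_equal(gt$coverage, c(1, 0.5))
  expect_identical(nrow(groundTruth(smallSimConfig())), 0L)
})

test_that("phase scrambling preserves the amplitude spectrum", {
  set.seed(21)
  x <- rnorm(256)
  y <- phaseScramble(x)
  expect_equal(Mod(fft(y))[2:128], Mod(fft(x))[2:128], tolerance = 1e-8)
  expect_gt(max(abs(x - y)), 0.1)  # actually scrambled
})

test_that("sampled planted-edge sets have disjoint endpoints in order", {
  set.seed(2)
  m <- toyMontage(8)
  pe <- samplePlantedEdges(m, "beta", 4, 0.3, 0.01)
  expect_identical(nrow(pe), 4L)
  expect_identical(anyDuplicated(c(pe$chanA, pe$chanB)), 0L)
  labs <- montageLabels(m)
  expect_true(all(match(pe$chanA, labs) < match(pe$chanB, labs)))
  expect_error(samplePlantedEdges(m, "beta", 5, 0.3, 0.01), "disjoint")
})
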