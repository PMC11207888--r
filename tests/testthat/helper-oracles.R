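# Shared fixtures and independent oracles for the test suite.

# Small montages keep the O(channels^2) stages cheap.
toyMontage <- function(n = 8) {
  labs <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
            "Fz", "Cz", "Pz", "F7", "F8", "T7", "T8", "Oz")[seq_len(n)]
  eegMontage(labs, reference = c("M1", "M2"))
}

makeEpochSet <- function(epochList, fs, labels, subjectId = "S01",
                         epochDuration = ncol(epochList[[1]]) / fs) {
  methods::new("EpochSet", epochs = epochList, samplingRate = fs,
               channelNames = labels, epochDuration = epochDuration,
               step = epochDuration / 2,
               epochIndex = seq_along(epochList) - 1L,
               retained = rep(TRUE, length(epochList)), band = "broadband",
               subjectId = subjectId)
}

# Independent naive PLI: explicit per-sample loop with its own wrapping.
naivePLI <- function(phaseA, phaseB) {
  stopifnot(length(phaseA) == length(phaseB))
  s <- 0
  for (t in seq_along(phaseA)) {
    d <- (phaseA[t] - phaseB[t]) %% (2 * pi)
    if (d > pi) d <- d - 2 * pi
    s <- s + sign(d)
  }
  abs(s / length(phaseA))
}

# Independent OLS reference via lm().
naiveOLS <- function(y, x) {
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r2 = sm$r.squared,
       p = unname(stats::coef(sm)[2, 4]))
}

# A length-n series with an exact target R^2 against x = 0:(n-1): the linear
# part plus an orthogonal residual scaled so SSres/SSreg = (1 - r2)/r2.
seriesWithR2 <- function(n, r2) {
  x <- seq_len(n) - 1
  xc <- x - mean(x)
  e <- xc^2
  e <- e - mean(e) - sum(e * xc) / sum(xc^2) * xc   # orthogonal to {1, x}
  e <- e * sqrt((1 - r2) / r2 * sum(xc^2) / sum(e^2))
  xc + e
}
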