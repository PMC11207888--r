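# FIR design and fast zero-phase application.
#
# Filters are Hamming windowed-sinc (signal::fir1) with a transition
# bandwidth of 25% of each band edge, bounded below by 2 Hz and above by the
# edge's distance to DC / Nyquist (the common neuroimaging rule). Symmetric
# linear-phase taps are applied by FFT linear convolution with exact
# group-delay compensation, which is zero-phase for symmetric kernels and
# orders of magnitude faster than time-domain filtfilt on long epochs.

.transitionBw <- function(low, high, fs) {
  nyq <- fs / 2
  tbLow <- min(max(0.25 * low, 2), low)
  tbHigh <- min(max(0.25 * high, 2), nyq - high)
  max(min(tbLow, tbHigh), fs / 2^14)  # keep the order bounded
}

# Odd-length (type I) linear-phase taps for a band-pass.
.designBandpass <- function(low, high, fs) {
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stopf("band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
          low, high, nyq)
  tb <- .transitionBw(low, high, fs)
  ord <- ceiling(3.3 * fs / tb)
  ord <- ord + ord %% 2L  # even order -> odd length, integer group delay
  signal::fir1(ord, c(low, high) / nyq, type = "pass")
}

.designBandstop <- function(low, high, fs) {
  nyq <- fs / 2
  tb <- 2
  ord <- ceiling(3.3 * fs / tb)
  ord <- ord + ord %% 2L
  signal::fir1(ord, c(low, high) / nyq, type = "stop")
}

.designLowpass <- function(cutoff, fs, tb) {
  ord <- ceiling(3.3 * fs / tb)
  ord <- ord + ord %% 2L
  signal::fir1(ord, cutoff / (fs / 2), type = "low")
}

# Zero-phase application of symmetric odd-length taps to a channels x samples
# matrix (or a vector). FFT linear convolution; output trimmed at the group
# delay so in-band components incur no shift.
.applyFIR <- function(x, h) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  L <- length(h)
  stopifnot(L %% 2L == 1L)
  delay <- (L - 1L) / 2L
  nfft <- stats::nextn(n + L - 1L, 2)
  H <- stats::fft(c(h, numeric(nfft - L)))
  X <- stats::mvfft(rbind(t(x), matrix(0, nfft - n, nrow(x))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  out <- t(y[delay + seq_len(n), , drop = FALSE])
  if (vec) out[1L, ] else out
}

# Rational approximation p/q of a rate ratio (q bounded).
.rationalRatio <- function(r, maxDen = 1024L, tol = 1e-9) {
  for (q in seq_len(maxDen)) {
    p <- round(r * q)
    if (p >= 1 && abs(p / q - r) < tol) return(c(p = p, q = q))
  }
  stopf("cannot express rate ratio %g as a small rational p/q", r)
}
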