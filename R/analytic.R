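# Hilbert analytic signal, instantaneous phase, phase differences, and the
# Phase Lag Index itself.
#
# The analytic signal w(t) = x(t) + i * H[x](t) is built in the frequency
# domain: the DFT's positive frequencies are doubled, negative frequencies
# zeroed (DC and Nyquist kept). Its argument is the instantaneous phase and
# its modulus the instantaneous amplitude. The PLI of two channels is the
# absolute mean sign of their wrapped instantaneous phase difference:
# perfectly consistent non-zero lag gives 1, symmetric or zero-centred lag
# distributions give 0, so zero-lag (volume-conducted) mixtures do not
# register.

#' Discrete analytic signal
#'
#' @param x Real numeric vector (length >= 2).
#' @return Complex vector `w` with `Re(w) == x`; `Arg(w)` is the
#'   instantaneous phase in (-pi, pi] and `Mod(w)` the amplitude envelope.
#' @examples
#' t <- seq(0, 1, by = 1 / 256)[-257]
#' w <- analyticSignal(cos(2 * pi * 10 * t))
#' all.equal(Re(w), cos(2 * pi * 10 * t))
#' @export
analyticSignal <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stopf("analyticSignal needs a real series of length >= 2")
  if (all(x == 0))
    stopf("analyticSignal is undefined for an all-zero series (no phase)")
  drop(.analyticMatrix(matrix(x, nrow = 1L)))
}

# Channels x samples matrix version (vectorized over channels via mvfft).
.analyticMatrix <- function(m) {
  n <- ncol(m)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  X <- stats::mvfft(t(m))
  t(stats::mvfft(X * h, inverse = TRUE)) / n
}

#' Instantaneous phase and amplitude
#'
#' Convenience accessors for the polar form of an analytic signal.
#'
#' @param w Complex vector from [analyticSignal()].
#' @return Numeric vector: phase in (-pi, pi], or non-negative amplitude.
#' @export
instantaneousPhase <- function(w) Arg(w)

#' @rdname instantaneousPhase
#' @export
instantaneousAmplitude <- function(w) Mod(w)

#' Wrapped instantaneous phase difference between two signals
#'
#' @param a,b Analytic signals (complex vectors) or phase vectors (numeric,
#'   radians). Must have equal length.
#' @return Numeric vector of phase differences `phase(a) - phase(b)` wrapped
#'   to (-pi, pi].
#' @export
phaseDifference <- function(a, b) {
  pa <- if (is.complex(a)) Arg(a) else a
  pb <- if (is.complex(b)) Arg(b) else b
  if (length(pa) != length(pb))
    stopf("phase series differ in length (%d vs %d)", length(pa), length(pb))
  wrapPhase(pa - pb)
}

#' Phase Lag Index of a phase-difference series
#'
#' `pli(d)` is `|mean(sign(d))|` with `sign(0) = 0`, so identical channels
#' (difference identically zero) score exactly 0 and a constant non-zero
#' lag scores exactly 1. Values are bounded in `[0, 1]`.
#'
#' @param d Numeric vector of wrapped phase differences (radians).
#' @return A single number in `[0, 1]`.
#' @examples
#' pli(rep(pi / 2, 100))            # 1: perfectly consistent positive lag
#' pli(rep(0, 100))                 # 0: zero lag is discounted
#' pli(c(0.3, 0.8, -0.2, -0.4))     # 0: balanced signs
#' @export
pli <- function(d) {
  if (!length(d)) stopf("pli of an empty series is undefined")
  abs(mean(sign(d)))
}
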