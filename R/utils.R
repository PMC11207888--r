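# Small shared helpers: phase wrapping, deterministic seed streams, edge keys.

#' Wrap phase values into (-pi, pi]
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector with every element mapped into the half-open
#'   interval (-pi, pi].
#' @examples
#' wrapPhase(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrapPhase <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

# Deterministic 32-bit seed derived from (master, subject, epoch).
# Exact in double arithmetic: master < 2^31 so master * 1009 < 2^41 << 2^53.
seedFor <- function(master, subject = 0L, epoch = 0L, stream = 0L) {
  as.integer((as.numeric(master) * 1009 + as.numeric(subject) * 10007 +
                as.numeric(epoch) * 101 + as.numeric(stream) * 7919) %%
               2147483629)
}

# Canonical unordered edge identifier; endpoints are kept in montage order
# everywhere, so plain concatenation is stable.
edgeKey <- function(chanA, chanB) paste(chanA, chanB, sep = "--")

# Column-major upper-triangle edge table for a label vector, matching the
# ordering of m[upper.tri(m)] and of the compiled PLI kernel.
upperTriPairs <- function(labels) {
  n <- length(labels)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(chanA = labels[idx[, "row"]], chanB = labels[idx[, "col"]],
             stringsAsFactors = FALSE)
}

isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
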