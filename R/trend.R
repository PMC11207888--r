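# Edge-wise ordinary-least-squares trend detection across the session.
#
# For each connection, the PLI trajectory y over epochs is regressed on the
# epoch index x (y = b0 + b1 x + e, closed-form OLS). R^2 = 1 - SSres/SStot
# and the two-sided p-value of b1 = 0 comes from F(1, n-2) (identical to the
# t-test for a single regressor). Edges pass the gate when R^2 > r2Min AND
# p < alpha, both strict; at n = 20 and the default thresholds, R^2 > 0.25
# already implies p < 0.05, but the p-condition is kept for other n.
# No multiple-testing correction is applied (1891 tests are gated by the
# stated thresholds alone); `expectedNullPasses()` reports the implied
# family-wise expectation under the null.

#' Threshold configuration for the significance gate
#'
#' @param r2Min Minimum explained variance (exclusive), default 0.25.
#' @param alpha Significance level (exclusive), default 0.05.
#' @return List of class `thresholdConfig`.
#' @export
thresholdConfig <- function(r2Min = 0.25, alpha = 0.05) {
  stopifnot(r2Min >= 0, r2Min < 1, alpha > 0, alpha <= 1)
  structure(list(r2Min = r2Min, alpha = alpha), class = "thresholdConfig")
}

# Columnwise closed-form OLS of Y (n x m) on x; degenerate (constant or
# perfectly fit) columns handled explicitly.
.olsTrend <- function(Y, x) {
  n <- nrow(Y)
  if (n < 3L) stopf("trend regression needs at least 3 epochs (got %d)", n)
  if (is.unsorted(x, strictly = TRUE))
    stopf("epoch times must be strictly increasing")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ym <- colMeans(Y)
  slope <- as.numeric(crossprod(xc, Y)) / sxx
  intercept <- ym - slope * mean(x)
  ssTot <- colSums(Y^2) - n * ym^2
  ssReg <- slope^2 * sxx
  ssRes <- pmax(ssTot - ssReg, 0)
  r2 <- ifelse(ssTot > 0, 1 - ssRes / ssTot, 0)
  r2 <- pmin(pmax(r2, 0), 1)
  Fstat <- ifelse(ssRes > 0, (n - 2) * r2 / (1 - r2), Inf)
  p <- ifelse(ssTot > 0,
              stats::pf(Fstat, 1, n - 2, lower.tail = FALSE),
              1)
  slope[ssTot == 0] <- 0
  data.frame(n = n, intercept = intercept, slope = slope, r2 = r2, p = p)
}

#' OLS trend of one edge's PLI trajectory
#'
#' @param y Numeric vector of PLI values across epochs (length >= 3).
#' @param x Epoch times; defaults to the index `0:(n-1)`, so the slope is in
#'   PLI units per epoch step (any affine recoding of `x` leaves R^2, p and
#'   the slope sign unchanged).
#' @return One-row data.frame: `n`, `intercept`, `slope`, `r2`, `p`.
#'   A constant `y` returns slope 0, R^2 0, p 1 by convention.
#' @examples
#' fitEdgeTrend(0.2 + 0.01 * (0:19))   # perfect line: R^2 = 1
#' fitEdgeTrend(rep(0.3, 10))          # degenerate: p = 1
#' @export
fitEdgeTrend <- function(y, x = seq_along(y) - 1) {
  if (length(y) != length(x)) stopf("y and x differ in length")
  .olsTrend(matrix(y, ncol = 1L), x)
}

#' Trend table for every edge of a PLI stack
#'
#' @param stack A `PLIStack` (edges x epochs).
#' @param cfg A [thresholdConfig()].
#' @return data.frame with one row per edge: `chanA`, `chanB`, `n`,
#'   `intercept`, `slope`, `r2`, `p`, `significant`.
#' @export
subjectTrends <- function(stack, cfg = thresholdConfig()) {
  W <- pliWeights(stack)
  x <- SummarizedExperiment::colData(stack)$epochIndex
  fit <- .olsTrend(t(W), as.numeric(x))
  et <- edgeTable(stack)
  out <- cbind(et, fit)
  out$significant <- out$r2 > cfg$r2Min & out$p < cfg$alpha
  out
}

#' Gate a trend table by the significance thresholds
#'
#' Keeps edges with `r2 > r2Min` and `p < alpha` (strict inequalities).
#'
#' @param trends data.frame as from [subjectTrends()] (needs `r2`, `p`,
#'   `slope`, `chanA`, `chanB`).
#' @param cfg A [thresholdConfig()].
#' @return data.frame of significant edges with their slopes.
#' @export
significantEdges <- function(trends, cfg = thresholdConfig()) {
  keep <- trends$r2 > cfg$r2Min & trends$p < cfg$alpha
  out <- trends[keep, c("chanA", "chanB", "slope", "r2", "p")]
  rownames(out) <- NULL
  out
}

#' Trends and gated edge set for one subject and band
#'
#' @param stack A `PLIStack`.
#' @param cfg A [thresholdConfig()].
#' @return List with the full `trends` table and the gated `edges` set.
#' @export
perSubjectTrends <- function(stack, cfg = thresholdConfig()) {
  tr <- subjectTrends(stack, cfg)
  list(trends = tr, edges = significantEdges(tr, cfg))
}

#' Expected null passes of the joint gate
#'
#' Number of edges expected to pass `R^2 > r2Min & p < alpha` when every
#' trajectory is pure i.i.d. noise: `nEdges * P(F(1, n-2) > max(Fr2, Fa))`.
#' Reported alongside results to flag the family-wise expectation of the
#' uncorrected gate.
#'
#' @param n Number of epochs per fit.
#' @param nEdges Number of tested edges.
#' @param cfg A [thresholdConfig()].
#' @return Expected count (numeric).
#' @export
expectedNullPasses <- function(n = 20, nEdges = 1891,
                               cfg = thresholdConfig()) {
  fR2 <- (n - 2) * cfg$r2Min / (1 - cfg$r2Min)
  fAlpha <- stats::qf(cfg$alpha, 1, n - 2, lower.tail = FALSE)
  nEdges * stats::pf(max(fR2, fAlpha), 1, n - 2, lower.tail = FALSE)
}
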