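# Group-level analysis: individual-network (IN) prevalence, shared-edge
# consensus, topographic classification, global-network (GN) averaging and
# regression, and IN/GN overlap summaries.

#' Edge prevalence across subjects
#'
#' Counts, for every edge significant in at least one subject, how many
#' subjects carry it, and records the contributing subjects and their
#' slopes. Counts are invariant to the order of subjects.
#'
#' @param inSets Named list of per-subject significant-edge tables (as from
#'   [significantEdges()]), all in the same band and channel space.
#' @param nSubjects Cohort size used for the denominator (defaults to
#'   `length(inSets)`).
#' @return data.frame with `chanA`, `chanB`, `count`, `fraction`, and
#'   list-columns `subjects` and `slopes`, sorted by decreasing count.
#' @export
prevalence <- function(inSets, nSubjects = length(inSets)) {
  if (is.null(names(inSets)))
    names(inSets) <- sprintf("S%02d", seq_along(inSets))
  rows <- do.call(rbind, lapply(names(inSets), function(s) {
    es <- inSets[[s]]
    if (!nrow(es)) return(NULL)
    data.frame(key = edgeKey(es$chanA, es$chanB), chanA = es$chanA,
               chanB = es$chanB, subject = s, slope = es$slope,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    return(data.frame(chanA = character(), chanB = character(),
                      count = integer(), fraction = numeric(),
                      subjects = I(list()), slopes = I(list()),
                      stringsAsFactors = FALSE))
  }
  sp <- split(rows, rows$key)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(chanA = g$chanA[1L], chanB = g$chanB[1L],
               count = nrow(g), fraction = nrow(g) / nSubjects,
               subjects = I(list(g$subject)), slopes = I(list(g$slope)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$count, out$chanA, out$chanB), ]
  rownames(out) <- NULL
  attr(out, "nSubjects") <- nSubjects
  out
}

#' Edges shared by at least a fraction of subjects
#'
#' Applies the prevalence threshold (default: present in >= 40% of
#' subjects, i.e. >= 9 of 21) and assigns each surviving edge a consensus
#' slope sign: the sign of the mean slope over contributing subjects, with
#' exact ties reported as sign 0.
#'
#' @param prev Prevalence table from [prevalence()].
#' @param threshold Minimum subject fraction (inclusive), default 0.40.
#' @return data.frame with `chanA`, `chanB`, `count`, `fraction`,
#'   `consensusSign`, `meanSlope`.
#' @export
sharedEdges <- function(prev, threshold = 0.40) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- prev[prev$fraction >= threshold, , drop = FALSE]
  meanSlope <- vapply(keep$slopes, function(s) mean(unlist(s)), numeric(1))
  out <- data.frame(chanA = keep$chanA, chanB = keep$chanB,
                    count = keep$count, fraction = keep$fraction,
                    consensusSign = sign(meanSlope), meanSlope = meanSlope,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tally consensus slope directions
#'
#' @param shared Shared-edge table from [sharedEdges()].
#' @return Named integer vector: `positive`, `negative`, `tied` (their sum
#'   is the number of shared edges).
#' @export
slopeTally <- function(shared) {
  c(positive = sum(shared$consensusSign > 0),
    negative = sum(shared$consensusSign < 0),
    tied = sum(shared$consensusSign == 0))
}

#' Topographic classification of edges
#'
#' Classifies each edge from its endpoints' 10-20 suffixes: both left ->
#' `intra-left`; both right -> `intra-right`; one of each ->
#' `interhemispheric`; any midline endpoint -> `midline-involving`. The four
#' classes partition every edge set.
#'
#' @param edges data.frame with `chanA`, `chanB`.
#' @return The input with a `topography` factor column appended.
#' @export
classifyEdges <- function(edges) {
  sa <- channelSide(edges$chanA)
  sb <- channelSide(edges$chanB)
  cls <- ifelse(sa == "midline" | sb == "midline", "midline-involving",
                ifelse(sa == sb,
                       ifelse(sa == "left", "intra-left", "intra-right"),
                       "interhemispheric"))
  edges$topography <- factor(cls, levels = c("intra-left", "intra-right",
                                             "interhemispheric",
                                             "midline-involving"))
  edges
}

#' Number of distinct channels touched by an edge set
#'
#' @param edges data.frame with `chanA`, `chanB`.
#' @return Integer count of unique endpoint labels.
#' @export
uniqueNodes <- function(edges) {
  length(unique(c(edges$chanA, edges$chanB)))
}

#' Global network: edge-wise average across subjects
#'
#' For one band, averages the individual PLI networks edge-by-edge and
#' epoch-by-epoch into the group-level stack. All subjects must be on the
#' same epoch grid.
#'
#' @param stacks List of `PLIStack` (one per subject, same band).
#' @return A `PLIStack` with `subjectId` `"GN"`.
#' @export
gnAverage <- function(stacks) {
  grid <- SummarizedExperiment::colData(stacks[[1]])$epochIndex
  for (s in stacks) {
    if (!identical(SummarizedExperiment::colData(s)$epochIndex, grid))
      stopf("subjects are on different epoch grids; cannot average")
    if (!identical(dim(pliWeights(s)), dim(pliWeights(stacks[[1]]))))
      stopf("subjects have different network dimensions")
  }
  W <- Reduce(`+`, lapply(stacks, pliWeights)) / length(stacks)
  pliStack(W, S4Vectors::metadata(stacks[[1]])$labels, epochIndex = grid,
           subjectId = "GN", band = bandName(stacks[[1]]))
}

#' Significant edges of the global network
#'
#' Runs the same edge-wise trend regression and gate on the group-averaged
#' stack.
#'
#' @param gn `PLIStack` from [gnAverage()].
#' @param cfg A [thresholdConfig()].
#' @return List: full `trends` table, gated `edges` set, and `count`.
#' @export
gnSignificant <- function(gn, cfg = thresholdConfig()) {
  res <- perSubjectTrends(gn, cfg)
  res$count <- nrow(res$edges)
  res
}

#' IN/GN shared-connection percentages
#'
#' For each subject, the percentage of the GN's significant edges that are
#' also significant in that subject's individual network:
#' `100 * |IN_s intersect GN| / |GN|`. The summary reports the mean,
#' population standard deviation (divide by n; recorded in the output),
#' minimum and maximum across subjects.
#'
#' @param inSets Named list of per-subject significant-edge tables.
#' @param gnSet GN significant-edge table (from `gnSignificant()$edges`).
#' @return List with `perSubject` (named percent vector), `mean`, `sd`,
#'   `min`, `max`, `nGn`, `sdType`. If the GN set is empty the percentages
#'   are undefined: all `NA` with a warning.
#' @export
inGnOverlap <- function(inSets, gnSet) {
  if (is.null(names(inSets)))
    names(inSets) <- sprintf("S%02d", seq_along(inSets))
  nGn <- nrow(gnSet)
  if (nGn == 0L) {
    warning("GN edge set is empty; overlap percentages are undefined")
    pct <- stats::setNames(rep(NA_real_, length(inSets)), names(inSets))
    return(list(perSubject = pct, mean = NA_real_, sd = NA_real_,
                min = NA_real_, max = NA_real_, nGn = 0L,
                sdType = "population"))
  }
  gKeys <- edgeKey(gnSet$chanA, gnSet$chanB)
  pct <- vapply(inSets, function(es) {
    100 * sum(edgeKey(es$chanA, es$chanB) %in% gKeys) / nGn
  }, numeric(1))
  list(perSubject = pct, mean = mean(pct),
       sd = sqrt(mean((pct - mean(pct))^2)),  # population convention
       min = min(pct), max = max(pct), nGn = nGn, sdType = "population")
}

#' Per-band report of the full group analysis
#'
#' Assembles, for every band, the quantities the analysis is after: the GN
#' significant-connection count, the IN/GN overlap summary, the shared-edge
#' list with consensus signs and topography, the slope tally, and the
#' prevalence distribution (explicit bin edges on the subject fraction).
#'
#' @param stacksBySubject List (subjects) of named lists (bands) of
#'   `PLIStack`, as from [buildStacks()].
#' @param cfg A [thresholdConfig()].
#' @param sharedThreshold Prevalence threshold for [sharedEdges()].
#' @param prevalenceBreaks Bin edges (fractions in (0, 1]) for the
#'   prevalence histogram.
#' @return Named list (bands) of per-band result lists; attribute
#'   `"inSets"` holds the per-band, per-subject gated edge sets.
#' @export
bandReport <- function(stacksBySubject, cfg = thresholdConfig(),
                       sharedThreshold = 0.40,
                       prevalenceBreaks = seq(0, 1, by = 0.1)) {
  bands <- names(stacksBySubject[[1]])
  subjects <- vapply(stacksBySubject,
                     function(s) subjectId(s[[1]]), character(1))
  nSub <- length(stacksBySubject)
  inSetsByBand <- list()
  out <- lapply(bands, function(bn) {
    stacks <- lapply(stacksBySubject, `[[`, bn)
    inSets <- lapply(stacks, function(st) significantEdges(
      subjectTrends(st, cfg), cfg))
    names(inSets) <- subjects
    inSetsByBand[[bn]] <<- inSets
    prev <- prevalence(inSets, nSub)
    shared <- classifyEdges(sharedEdges(prev, sharedThreshold))
    gn <- gnSignificant(gnAverage(stacks), cfg)
    hist <- table(cut(prev$fraction, breaks = prevalenceBreaks,
                      include.lowest = FALSE))
    list(band = bn,
         gnCount = gn$count,
         gnEdges = gn$edges,
         overlap = inGnOverlap(inSets, gn$edges),
         shared = shared,
         slopeTally = slopeTally(shared),
         uniqueNodes = uniqueNodes(shared),
         prevalence = prev,
         prevalenceHist = hist,
         maxSharedFraction = if (nrow(prev)) max(prev$fraction) else 0,
         expectedNullPasses = expectedNullPasses(
           n = ncol(pliWeights(stacks[[1]])),
           nEdges = nrow(pliWeights(stacks[[1]])), cfg = cfg))
  })
  names(out) <- bands
  attr(out, "inSets") <- inSetsByBand
  out
}
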