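# Per-epoch PLI networks and per-band network stacks.

#' PLI network of one band-limited epoch
#'
#' Computes the Phase Lag Index for every unordered channel pair of a
#' band-limited epoch: analytic signal per channel, wrapped instantaneous
#' phase differences, then `|mean(sign(.))|` per pair. Weights are stored as
#' the column-major upper triangle (1891 values for 62 channels), the same
#' ordering as `edgeTable()`.
#'
#' @param mat Channels x samples numeric matrix, already band-pass filtered.
#' @param montage `EEGMontage` whose network labels match the rows of `mat`.
#' @param band Band name recorded in the result.
#' @param epochIndex Epoch position recorded in the result.
#' @param subjectId Subject identifier recorded in the result.
#' @return A `PLINetwork`; use [pliWeights()] or `as.matrix()` on it.
#' @export
epochNetwork <- function(mat, montage, band = "broadband",
                         epochIndex = 0L, subjectId = "subject") {
  labs <- montageLabels(montage)
  if (nrow(mat) != length(labs))
    stopf("epoch has %d channels but montage defines %d network channels",
          nrow(mat), length(labs))
  ph <- Arg(.analyticMatrix(mat))
  w <- .pliUpperCpp(t(ph))
  methods::new("PLINetwork", weights = as.numeric(w), labels = labs,
               band = band, epochIndex = as.integer(epochIndex),
               subjectId = subjectId)
}

#' @rdname pliStack
#' @export
setMethod("pliWeights", "PLINetwork", function(x) x@weights)

#' @rdname pliStack
#' @export
setMethod("bandName", "PLINetwork", function(x) x@band)

#' @describeIn epochNetwork Densify a `PLINetwork` into the symmetric
#'   adjacency matrix (zero diagonal).
#' @param x A `PLINetwork`.
#' @param ... Ignored.
#' @export
setMethod("as.matrix", "PLINetwork", function(x, ...) {
  n <- length(x@labels)
  m <- matrix(0, n, n, dimnames = list(x@labels, x@labels))
  m[upper.tri(m)] <- x@weights
  m + t(m)
})

setMethod("show", "PLINetwork", function(object) {
  cat(sprintf("PLINetwork: %s / %s band, epoch %d, %d edges (mean PLI %.3f)\n",
              object@subjectId, object@band, object@epochIndex,
              length(object@weights), mean(object@weights)))
})

#' Stack of PLI networks across epochs
#'
#' A `PLIStack` is a `SummarizedExperiment` whose `"pli"` assay holds the
#' edge x epoch weight matrix for one subject and one frequency band.
#' `rowData` carries the edge endpoints (`chanA`, `chanB`), `colData` the
#' epoch grid (`epochIndex`), and `metadata` the subject and band.
#'
#' @param weights Edges x epochs numeric matrix in `[0, 1]`.
#' @param labels Channel labels spanning the edge space.
#' @param epochIndex Integer epoch positions (strictly increasing).
#' @param subjectId,band Identifiers stored in `metadata()`.
#' @return A `PLIStack`.
#' @aliases bandName pliWeights PLIStack-class
#' @export
pliStack <- function(weights, labels, epochIndex = seq_len(ncol(weights)) - 1L,
                     subjectId = "subject", band = "broadband") {
  et <- upperTriPairs(labels)
  if (nrow(weights) != nrow(et))
    stopf("weights has %d rows but %d channel labels imply %d edges",
          nrow(weights), length(labels), nrow(et))
  rownames(weights) <- edgeKey(et$chanA, et$chanB)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(pli = weights),
    rowData = S4Vectors::DataFrame(chanA = et$chanA, chanB = et$chanB),
    colData = S4Vectors::DataFrame(
      epochIndex = as.integer(epochIndex),
      row.names = paste0("epoch", epochIndex)),
    metadata = list(subjectId = subjectId, band = band, labels = labels))
  methods::new("PLIStack", se)
}

#' @rdname pliStack
#' @export
setMethod("pliWeights", "PLIStack",
          function(x) SummarizedExperiment::assay(x, "pli"))

#' @rdname pliStack
#' @export
setMethod("bandName", "PLIStack", function(x) S4Vectors::metadata(x)$band)

#' @rdname pliStack
#' @export
setMethod("subjectId", "PLIStack", function(x) S4Vectors::metadata(x)$subjectId)

#' @rdname pliStack
#' @export
setMethod("edgeTable", "PLIStack", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(chanA = rd$chanA, chanB = rd$chanB, stringsAsFactors = FALSE)
})

#' Band-wise PLI stacks for one subject
#'
#' Runs the connectivity chain for every requested frequency band: each
#' retained epoch is band-pass filtered, Hilbert-transformed, and reduced to
#' its PLI network; networks are collected into one [pliStack()] per band.
#'
#' @param es `EpochSet` of broadband (or pre-filtered) epochs.
#' @param bands Band definition table, see [defaultBands()].
#' @param montage `EEGMontage` matching the epoch channels.
#' @return Named list of `PLIStack`, one per band.
#' @export
computeStacks <- function(es, bands = defaultBands(), montage = NULL) {
  labs <- if (is.null(montage)) es@channelNames else montageLabels(montage)
  if (!identical(labs, es@channelNames))
    stopf("montage channels do not match the epoch channels")
  keep <- which(es@retained)
  if (!length(keep)) stopf("no retained epochs")
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (b in seq_len(nrow(bands))) {
    h <- .designBandpass(bands$low[b], bands$high[b], es@samplingRate)
    w <- vapply(keep, function(i) {
      ph <- Arg(.analyticMatrix(.applyFIR(es@epochs[[i]], h)))
      as.numeric(.pliUpperCpp(t(ph)))
    }, numeric(length(labs) * (length(labs) - 1L) / 2L))
    out[[b]] <- pliStack(w, labs, epochIndex = es@epochIndex[keep],
                         subjectId = es@subjectId, band = bands$name[b])
  }
  out
}

#' Band-wise PLI stacks for a cohort
#'
#' @param epochSets List of `EpochSet`, one per subject, on aligned epoch
#'   grids.
#' @param bands Band definition table.
#' @return List (subjects) of named lists (bands) of `PLIStack`. An error is
#'   raised if subjects end up on different epoch grids (e.g. after
#'   different QC exclusions), since group averaging requires alignment.
#' @export
buildStacks <- function(epochSets, bands = defaultBands()) {
  stacks <- lapply(epochSets, computeStacks, bands = bands)
  grids <- lapply(stacks, function(s)
    SummarizedExperiment::colData(s[[1]])$epochIndex)
  if (length(unique(lapply(grids, identical, grids[[1]]))) &&
      !all(vapply(grids, identical, logical(1), grids[[1]])))
    stopf("subjects have mismatched epoch grids after QC; cannot align stacks")
  stacks
}
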