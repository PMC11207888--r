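# S4 class definitions. Constructors live next to the module logic
# (montage.R, preprocessing.R, simulate.R, network.R).

#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClass("EEGMontage",
         representation(labels = "character", reference = "character"))

setValidity("EEGMontage", function(object) {
  all <- c(object@labels, object@reference)
  if (anyDuplicated(all)) return("channel labels must be unique")
  if (length(object@labels) < 2L) return("need at least two network channels")
  bad <- !grepl("[0-9z]$", all, ignore.case = TRUE)
  if (any(bad))
    return(paste0("labels must end in a digit or 'z': ",
                  paste(all[bad], collapse = ", ")))
  TRUE
})

setClass("EEGRecording",
         representation(data = "matrix", samplingRate = "numeric",
                        channelNames = "character", subjectId = "character"))

setValidity("EEGRecording", function(object) {
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("samplingRate must be a single positive number")
  if (nrow(object@data) != length(object@channelNames))
    return("number of data rows must equal number of channel names")
  TRUE
})

setClass("EpochSet",
         representation(epochs = "list", samplingRate = "numeric",
                        channelNames = "character",
                        epochDuration = "numeric", step = "numeric",
                        epochIndex = "integer", retained = "logical",
                        band = "character", subjectId = "character"))

setValidity("EpochSet", function(object) {
  if (!length(object@epochs)) return("EpochSet must contain at least one epoch")
  dims <- vapply(object@epochs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all epochs must share the same channel x sample shape")
  if (dims[1, 1] != length(object@channelNames))
    return("epoch rows must match the channel names")
  if (length(object@epochIndex) != length(object@epochs))
    return("epochIndex must have one entry per epoch")
  if (is.unsorted(object@epochIndex, strictly = TRUE))
    return("epochIndex must be strictly increasing (temporal order)")
  if (length(object@retained) != length(object@epochs))
    return("retained mask must have one entry per epoch")
  TRUE
})

setClass("PLINetwork",
         representation(weights = "numeric", labels = "character",
                        band = "character", epochIndex = "integer",
                        subjectId = "character"))

setValidity("PLINetwork", function(object) {
  ne <- length(object@labels) * (length(object@labels) - 1L) / 2L
  if (length(object@weights) != ne)
    return(sprintf("expected %d edge weights for %d channels, got %d",
                   ne, length(object@labels), length(object@weights)))
  if (any(!is.finite(object@weights)) ||
      any(object@weights < 0) || any(object@weights > 1))
    return("PLI weights must be finite and within [0, 1]")
  TRUE
})

#' @rdname pliStack
#' @export
setClass("PLIStack", contains = "SummarizedExperiment")

setValidity("PLIStack", function(object) {
  if (!"pli" %in% SummarizedExperiment::assayNames(object))
    return("PLIStack requires an assay named 'pli'")
  a <- SummarizedExperiment::assay(object, "pli")
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1))
    return("PLI weights must be finite and within [0, 1]")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chanA", "chanB") %in% colnames(rd)))
    return("rowData must contain chanA and chanB")
  cd <- SummarizedExperiment::colData(object)
  if (!"epochIndex" %in% colnames(cd))
    return("colData must contain epochIndex")
  if (is.unsorted(cd$epochIndex, strictly = TRUE))
    return("epoch indices must be strictly increasing")
  TRUE
})

setClass("SimConfig",
         representation(nSubjects = "integer", montage = "EEGMontage",
                        samplingRate = "numeric", nEpochs = "integer",
                        epochDuration = "numeric", plantedEdges = "data.frame",
                        noiseSd = "numeric", commonSourceGain = "numeric",
                        edgeAmplitude = "numeric", masterSeed = "integer",
                        bands = "data.frame"))

setValidity("SimConfig", function(object) {
  if (object@nSubjects < 1L) return("nSubjects must be >= 1")
  if (object@nEpochs < 3L)
    return("nEpochs must be >= 3 (trend regression needs residual df >= 1)")
  if (object@samplingRate < 2 * max(object@bands$high))
    return("samplingRate must be at least twice the highest band edge (Nyquist)")
  if (object@noiseSd < 0 || object@commonSourceGain < 0)
    return("noise parameters must be non-negative")
  pe <- object@plantedEdges
  if (nrow(pe)) {
    need <- c("chanA", "chanB", "band", "phaseLag", "baseCoupling",
              "couplingSlope")
    if (!all(need %in% names(pe)))
      return(paste("plantedEdges needs columns:", paste(need, collapse = ", ")))
    labs <- montageLabels(object@montage)
    if (!all(pe$chanA %in% labs) || !all(pe$chanB %in% labs))
      return("planted edge endpoints must be network channels of the montage")
    if (any(pe$chanA == pe$chanB))
      return("planted edges must connect two distinct channels")
    if (!all(pe$band %in% object@bands$name))
      return("planted edge bands must be defined in the band table")
    tol <- 1e-6
    if (any(pe$phaseLag <= tol | pe$phaseLag >= pi - tol))
      return("phase lags must lie strictly inside (0, pi): zero-lag coupling is invisible to PLI")
    kEnd <- pe$baseCoupling + pe$couplingSlope * (object@nEpochs - 1L)
    if (any(pe$baseCoupling < 0 | pe$baseCoupling > 1 | kEnd < 0 | kEnd > 1))
      return("coupling must stay within [0, 1] at every epoch")
    if (!is.null(pe$subjects)) {
      ok <- vapply(pe$subjects, function(s) {
        is.null(s) || (all(s >= 1) && all(s <= object@nSubjects))
      }, logical(1))
      if (!all(ok)) return("planted edge subject indices out of range")
    }
  }
  TRUE
})
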