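# Generics for the accessor surface shared across classes.

#' @rdname eegMontage
#' @param x An object with a channel montage.
#' @export
setGeneric("montageLabels", function(x) standardGeneric("montageLabels"))

#' @rdname eegMontage
#' @export
setGeneric("referenceLabels", function(x) standardGeneric("referenceLabels"))

#' @rdname eegMontage
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname eegMontage
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname eegRecording
#' @param x An object carrying sampled signals.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname eegRecording
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname eegRecording
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @rdname epochSet
#' @param x An `EpochSet` or similar epoch container.
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' @rdname epochSet
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname epochSet
#' @export
setGeneric("retainedMask", function(x) standardGeneric("retainedMask"))

#' @rdname epochSet
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname pliStack
#' @param x A `PLIStack` or `PLINetwork`.
#' @export
setGeneric("bandName", function(x) standardGeneric("bandName"))

#' @rdname pliStack
#' @export
setGeneric("pliWeights", function(x) standardGeneric("pliWeights"))
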