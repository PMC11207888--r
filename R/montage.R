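# Electrode montage bookkeeping: 10-20/10-10 label conventions, hemispheric
# classification, and the edge (channel-pair) space.

# 64-channel Waveguard-style cap: 62 scalp electrodes plus the two mastoids
# used for re-referencing.
.waveguardScalp <- c(
  "Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
  "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
  "POz", "O1", "Oz", "O2", "AF7", "AF3", "AF4", "AF8",
  "F5", "F1", "F2", "F6", "FC3", "FCz", "FC4",
  "C5", "C1", "C2", "C6", "CP3", "CPz", "CP4",
  "P5", "P1", "P2", "P6", "PO5", "PO3", "PO4", "PO6",
  "FT7", "FT8", "TP7", "TP8", "PO7", "PO8")

#' EEG montage: network channels plus reference electrodes
#'
#' An `EEGMontage` holds the ordered scalp-channel labels that span the
#' connectivity network, together with the reference electrodes (mastoids by
#' default) that are subtracted during re-referencing and excluded from the
#' network. Labels follow the extended 10-20 convention: a trailing odd digit
#' marks the left hemisphere, an even digit the right, and a trailing "z" the
#' midline.
#'
#' @param labels Character vector of network channel labels.
#' @param reference Character vector of reference channel labels.
#' @return An `EEGMontage` object.
#' @examples
#' m <- makeDefaultMontage()
#' length(montageLabels(m))   # 62
#' nEdges(m)                  # 1891 unique channel pairs
#' channelSide(c("C3", "C4", "Cz"))
#' @aliases montageLabels referenceLabels nEdges edgeTable
#' @export
eegMontage <- function(labels, reference = character()) {
  methods::new("EEGMontage", labels = as.character(labels),
               reference = as.character(reference))
}

#' Default 62-channel montage with mastoid references
#'
#' Returns the package's standard 64-electrode cap layout: 62 scalp channels
#' forming the network space (hence 62 * 61 / 2 = 1891 unique connections)
#' and the left/right mastoids `M1`/`M2` as reference electrodes.
#'
#' @return An `EEGMontage` with 62 network labels and references `M1`, `M2`.
#' @export
makeDefaultMontage <- function() {
  eegMontage(.waveguardScalp, reference = c("M1", "M2"))
}

#' Classify channel labels by hemisphere
#'
#' @param labels Character vector of 10-20 style labels (or an `EEGMontage`).
#' @return Character vector with values `"left"`, `"right"`, `"midline"`.
#' @export
channelSide <- function(labels) {
  if (methods::is(labels, "EEGMontage")) labels <- montageLabels(labels)
  out <- character(length(labels))
  zl <- grepl("z$", labels, ignore.case = TRUE)
  out[zl] <- "midline"
  num <- grepl("[0-9]$", labels)
  bad <- !zl & !num
  if (any(bad))
    stopf("cannot classify label(s): %s", paste(labels[bad], collapse = ", "))
  digits <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1",
                                            labels[num])))
  out[num] <- ifelse(digits %% 2L == 1L, "left", "right")
  out
}

#' @rdname eegMontage
#' @export
setMethod("montageLabels", "EEGMontage", function(x) x@labels)

#' @rdname eegMontage
#' @export
setMethod("referenceLabels", "EEGMontage", function(x) x@reference)

#' @rdname eegMontage
#' @export
setMethod("nEdges", "EEGMontage", function(x) {
  n <- length(x@labels)
  as.integer(n * (n - 1L) / 2L)
})

#' @rdname eegMontage
#' @export
setMethod("edgeTable", "EEGMontage", function(x) upperTriPairs(x@labels))

setMethod("show", "EEGMontage", function(object) {
  cat(sprintf("EEGMontage: %d network channels, %d reference (%s), %d edges\n",
              length(object@labels), length(object@reference),
              paste(object@reference, collapse = "/"), nEdges(object)))
  side <- channelSide(object@labels)
  cat(sprintf("  left %d | midline %d | right %d\n",
              sum(side == "left"), sum(side == "midline"),
              sum(side == "right")))
})
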