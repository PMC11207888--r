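# Configurable end-to-end pipeline: simulate (or read) recordings, build
# band-wise PLI stacks, run the trend gate per subject, aggregate the group
# analysis, and write tables plus a reproducibility manifest.

.pipelineKeys <- c("simulation", "inputFiles", "bands", "thresholds",
                   "sharedThreshold", "reference", "qcThresholdDb",
                   "outDir", "notch")

#' Pipeline configuration
#'
#' Validates and freezes the parameters of a full run. Exactly one of
#' `simulation` (a [simConfig()]) or `inputFiles` (EDF paths) must be given.
#' Unknown keys are rejected.
#'
#' @param simulation A `SimConfig`, or `NULL` when reading files.
#' @param inputFiles Character vector of EDF paths, or `NULL`.
#' @param bands Band table, see [defaultBands()].
#' @param thresholds A [thresholdConfig()].
#' @param sharedThreshold Prevalence threshold for shared edges.
#' @param reference Reference labels for the real-data path.
#' @param qcThresholdDb QC gate threshold (real-data path).
#' @param notch Mains frequency for the real-data path (`NULL` = off).
#' @param outDir Output directory, or `NULL` to skip writing.
#' @param ... Catches unknown keys (an error).
#' @return List of class `pipelineConfig`.
#' @export
pipelineConfig <- function(simulation = NULL, inputFiles = NULL,
                           bands = defaultBands(),
                           thresholds = thresholdConfig(),
                           sharedThreshold = 0.40,
                           reference = c("M1", "M2"), qcThresholdDb = 6,
                           notch = NULL, outDir = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stopf("unknown pipeline configuration key(s): %s",
          paste(names(extra), collapse = ", "))
  if (is.null(simulation) == is.null(inputFiles))
    stopf("give exactly one of `simulation` or `inputFiles`")
  stopifnot(inherits(thresholds, "thresholdConfig"),
            sharedThreshold > 0, sharedThreshold <= 1)
  structure(list(simulation = simulation, inputFiles = inputFiles,
                 bands = bands, thresholds = thresholds,
                 sharedThreshold = sharedThreshold, reference = reference,
                 qcThresholdDb = qcThresholdDb, notch = notch,
                 outDir = outDir),
            class = "pipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Synthetic path: simulate every subject on the analysis grid, baseline-
#' correct, band-decompose, and compute PLI stacks. File path: read each EDF
#' and run [preprocessRecording()] first. Then per subject and band the edge
#' trends are fitted and gated, and the group stage (prevalence, shared
#' edges, GN, IN/GN overlap) is assembled into a [bandReport()]. When
#' `outDir` is set, long-format edge tables (CSV), the report (JSON) and a
#' run manifest with per-file checksums are written.
#'
#' @param config A [pipelineConfig()].
#' @return The band report (invisibly when writing to disk).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  t0 <- Sys.time()
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    epochSets <- lapply(seq_len(sim@nSubjects), function(s) {
      message(sprintf("[simulate] subject %d/%d", s, sim@nSubjects))
      baselineCorrect(simulateSubject(sim, s))
    })
  } else {
    epochSets <- lapply(config$inputFiles, function(f) {
      message(sprintf("[read] %s", f))
      preprocessRecording(readEDF(f), reference = config$reference,
                          notch = config$notch,
                          qcThresholdDb = config$qcThresholdDb)
    })
  }
  for (es in epochSets) {
    dropped <- sum(!retainedMask(es))
    if (dropped) warning(sprintf("subject %s: %d epoch(s) excluded by QC",
                                 subjectId(es), dropped))
  }
  message("[connectivity] building PLI stacks")
  stacks <- buildStacks(epochSets, bands = config$bands)
  message("[group] trend gating and group analysis")
  report <- bandReport(stacks, cfg = config$thresholds,
                       sharedThreshold = config$sharedThreshold)
  for (bn in names(report)) {
    if (report[[bn]]$overlap$nGn == 0L)
      warning(sprintf("band %s: empty GN edge set", bn))
  }
  message(sprintf("[done] %.1f s elapsed",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  if (is.null(config$outDir)) return(report)
  writeBandReport(report, stacks, config)
  invisible(report)
}

# Long-format edge export: one row per subject x band x epoch x edge.
.stackLongFormat <- function(stacksBySubject) {
  do.call(rbind, lapply(stacksBySubject, function(byBand) {
    do.call(rbind, lapply(byBand, function(st) {
      W <- pliWeights(st)
      et <- edgeTable(st)
      grid <- SummarizedExperiment::colData(st)$epochIndex
      data.frame(subject = subjectId(st), band = bandName(st),
                 epoch = rep(grid, each = nrow(W)),
                 chanA = rep(et$chanA, times = ncol(W)),
                 chanB = rep(et$chanB, times = ncol(W)),
                 pli = as.numeric(W), stringsAsFactors = FALSE)
    }))
  }))
}

#' Write pipeline outputs and the run manifest
#'
#' @param report Band report from [bandReport()].
#' @param stacksBySubject Stacks from [buildStacks()].
#' @param config The [pipelineConfig()] that produced them (must carry
#'   `outDir`).
#' @return Output directory, invisibly.
#' @export
writeBandReport <- function(report, stacksBySubject, config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(config$outDir, "pli_long.csv")
  utils::write.csv(.stackLongFormat(stacksBySubject), p, row.names = FALSE)
  paths <- c(paths, p)
  for (bn in names(report)) {
    r <- report[[bn]]
    p <- file.path(config$outDir, sprintf("shared_edges_%s.csv", bn))
    utils::write.csv(r$shared, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  summ <- lapply(report, function(r) list(
    band = r$band, gnCount = r$gnCount,
    overlapMean = r$overlap$mean, overlapSd = r$overlap$sd,
    overlapMin = r$overlap$min, overlapMax = r$overlap$max,
    sdType = r$overlap$sdType,
    nShared = nrow(r$shared), slopeTally = as.list(r$slopeTally),
    uniqueNodes = r$uniqueNodes,
    expectedNullPasses = r$expectedNullPasses))
  p <- file.path(config$outDir, "report.json")
  jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)

  manifest <- list(
    package = "fatiguePLI",
    version = as.character(utils::packageVersion("fatiguePLI")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    masterSeed = if (!is.null(config$simulation))
      config$simulation@masterSeed else NA,
    thresholds = unclass(config$thresholds),
    sharedThreshold = config$sharedThreshold,
    bands = config$bands,
    checksums = as.list(tools::md5sum(paths)))
  mp <- file.path(config$outDir, "manifest.json")
  tmp <- paste0(mp, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, mp)  # atomic at run end
  invisible(config$outDir)
}
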