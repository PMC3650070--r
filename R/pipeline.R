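## One-shot orchestration: (optionally simulate) -> profile -> peaks ->
## NDR/occupancy -> group comparison -> report bundle.  The run
## configuration is a plain named list (a parameter bag, not a data
## object), overridable from a YAML file and echoed into the report.

.runDefaults <- function() {
  list(
    probes = NULL, signals = NULL, tss = NULL, groups = NULL,
    outDir = "nucleoprof_out",
    window = 30, step = 10, flank = 600, span = 0.05,
    minProminence = 0.05, minSeparation = 100,
    footprint = 160, alpha = 0.05, seed = 1L,
    groupA = NULL, groupB = NULL,
    simulateStage = NULL, nCells = 2000,
    logFile = NULL, logLevel = "info")
}

#' Build a pipeline run configuration
#'
#' Starts from the canonical defaults (30 bp window, 10 bp step, 600 bp
#' flank, lowess f = 0.05, 160 bp footprint, alpha = 0.05) and applies
#' overrides.  `simulateStage` switches the input source to the
#' simulator; otherwise `probes`, `signals` and `tss` must be file paths.
#'
#' @param ... overrides of the defaults listed above.
#' @param yamlFile optional YAML file of overrides (flags given in `...`
#'   win over the file).
#' @return named list of class `nucleoprofRunConfig`.
#' @export
makeRunConfig <- function(..., yamlFile = NULL) {
  cfg <- .runDefaults()
  if (!is.null(yamlFile)) {
    if (!file.exists(yamlFile))
      stop(sprintf("config file not found: %s", yamlFile), call. = FALSE)
    fromFile <- yaml::read_yaml(yamlFile)
    cfg[names(fromFile)] <- fromFile
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "nucleoprofRunConfig"
  cfg
}

.log <- function(cfg, fmt, ...) {
  line <- sprintf("[nucleoprof %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  message(line)
  if (!is.null(cfg$logFile)) cat(line, "\n", file = cfg$logFile, append = TRUE)
}

.needFile <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(sprintf("%s file not found: %s", what,
                 if (is.null(path)) "(not set)" else path), call. = FALSE)
  path
}

#' Run the full nucleosome-profiling pipeline
#'
#' Reads (or simulates) the inputs, builds the aggregate window and
#' smoothed tracks, calls and labels peaks, sizes the NDR, computes the
#' -1/+1 occupancy ratio, optionally compares two gene groups with the
#' per-window rank-sum test, writes every stage product as TSV under
#' `outDir` plus a machine-readable `summary.json`, and returns the
#' summary invisibly.  Identical configurations produce byte-identical
#' summaries.
#'
#' @param config a run configuration from [makeRunConfig()].
#' @return the summary list, invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "nucleoprofRunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulateStage)) {
    .log(config, "simulating '%s' stage (%d cells, seed %d)",
         config$simulateStage, config$nCells, config$seed)
    sim <- simulateExperiment(makeStageConfig(config$simulateStage,
                                              nCells = config$nCells,
                                              seed = config$seed))
    inDir <- file.path(config$outDir, "inputs")
    writeSimulation(sim, inDir)
    probes <- sim$probes; tss <- sim$tss; signal <- sim$signal
  } else {
    probes <- readProbes(.needFile(config$probes, "probe table"))
    tss <- readTss(.needFile(config$tss, "TSS annotation"))
    signal <- readSignalTable(.needFile(config$signals, "signal table"))
  }
  groups <- if (!is.null(config$groups)) {
    if (is.character(config$groups)) readGeneGroups(.needFile(config$groups,
                                                              "gene groups"))
    else config$groups
  }

  .log(config, "computing log2 ratios for %d signal rows", nrow(signal))
  ratios <- computeLog2Ratio(signal)
  repIds <- unique(ratios$replicate_id)
  concord <- NA_real_
  if (length(repIds) >= 2) {
    byRep <- lapply(repIds[1:2], function(r) {
      sel <- ratios[ratios$replicate_id == r, ]
      setNames(sel$log2_ratio, sel$probe_id)
    })
    concord <- replicateConcordance(byRep[[1]], byRep[[2]])
    .log(config, "replicate concordance r^2 = %.3f", concord)
  }
  avg <- suppressWarnings(averageReplicates(ratios))
  perProbe <- setNames(avg$log2_ratio, avg$probe_id)

  rel <- mapProbesToTss(probes, perProbe, tss, flank = config$flank)
  allGenes <- mcols(tss)$gene_id
  track <- aggregateWindows(rel, allGenes, width = config$window,
                            step = config$step, flank = config$flank)
  smooth <- smoothLowess(track, spanF = config$span)
  peaks <- callPeaks(smooth, minProminence = config$minProminence,
                     minSeparation = config$minSeparation)
  model <- fragmentSizeModel(footprint = config$footprint)
  ndr <- ndrWidth(peaks, model)
  ratio <- suppressWarnings(occupancyRatio(peaks))
  .log(config, "%d peaks called; NDR %s", nrow(peaksTable(peaks)),
       if (ndr@called) sprintf("%.0f bp", ndr@width) else "not called")

  trackDf <- data.frame(position = windowCenters(track),
                        value = meanSignal(track), n_points = nPoints(track))
  write.table(trackDf, file.path(config$outDir, "window_track.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  write.table(data.frame(position = trackPositions(smooth),
                         value = trackValues(smooth)),
              file.path(config$outDir, "smooth_track.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writePeaks(peaks, file.path(config$outDir, "peaks.tsv"))

  comparison <- NULL
  if (!is.null(groups) && !is.null(config$groupA) && !is.null(config$groupB)) {
    .log(config, "comparing '%s' vs '%s'", config$groupA, config$groupB)
    mA <- perGeneWindowMatrix(rel, .getGroup(groups, config$groupA),
                              width = config$window, step = config$step,
                              flank = config$flank)
    mB <- perGeneWindowMatrix(rel, .getGroup(groups, config$groupB),
                              width = config$window, step = config$step,
                              flank = config$flank)
    wt <- wilcoxonTrack(mA, mB, alpha = config$alpha)
    writeWilcoxonTrack(wt, file.path(config$outDir, "comparison.tsv"))
    comparison <- list(groupA = config$groupA, groupB = config$groupB,
                       nSignificant = sum(isSignificant(wt)),
                       significantCenters = windowCenters(wt)[isSignificant(wt)])
  }

  pk <- peaksTable(peaks)
  summary <- list(
    version = 1L,
    config = config[setdiff(names(config), c("logFile"))],
    replicateConcordance = concord,
    peaks = list(labels = pk$label, centers = pk$center,
                 amplitudes = pk$amplitude, spacings = peakSpacings(peaks)),
    ndr = list(called = ndr@called, separation = ndr@separation,
               width = ndr@width, footprint = ndr@footprint,
               reason = ndr@reason),
    occupancyRatio = ratio,
    comparison = comparison)
  jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, null = "null",
                       pretty = TRUE, force = TRUE)
  .log(config, "report written to %s", config$outDir)
  invisible(summary)
}
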