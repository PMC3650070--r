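## Accessors and show() methods.

#' @rdname WindowTrack-class
#' @aliases windowCenters,WindowTrack-method
setMethod("windowCenters", "WindowTrack", function(x) x@windowCenters)

#' @rdname WindowTrack-class
setMethod("meanSignal", "WindowTrack", function(x) x@meanSignal)

#' @rdname WindowTrack-class
setMethod("nPoints", "WindowTrack", function(x) x@nPoints)

#' @rdname WilcoxonTrack-class
#' @param x a `WilcoxonTrack`.
setMethod("windowCenters", "WilcoxonTrack", function(x) x@windowCenters)

#' @rdname WilcoxonTrack-class
setMethod("pValues", "WilcoxonTrack", function(x) x@pValue)

#' @rdname WilcoxonTrack-class
setMethod("isSignificant", "WilcoxonTrack", function(x) x@significant)

#' @rdname SmoothTrack-class
setMethod("trackPositions", "SmoothTrack", function(x) x@positions)

#' @rdname SmoothTrack-class
setMethod("trackValues", "SmoothTrack", function(x) x@value)

#' @rdname PeakSet-class
setMethod("peaksTable", "PeakSet", function(x) x@peaks)

#' @rdname FragmentSizeModel-class
setMethod("linkerRange", "FragmentSizeModel", function(x) x@linkerRange)

#' @rdname FragmentSizeModel-class
setMethod("spacingRange", "FragmentSizeModel", function(x) x@spacingRange)

#' @rdname FragmentSizeModel-class
setMethod("footprint", "FragmentSizeModel", function(x) x@footprint)

setMethod("show", "WindowTrack", function(object) {
  n <- length(object@windowCenters)
  cat(sprintf("WindowTrack: %d windows (%g bp wide, step %g bp), %d empty\n",
              n, object@windowWidth, object@step, sum(object@nPoints == 0L)))
  if (n) cat(sprintf("  span %g..%g bp; pooled observations: %d\n",
                     min(object@windowCenters), max(object@windowCenters),
                     sum(object@nPoints)))
})

setMethod("show", "SmoothTrack", function(object) {
  cat(sprintf("SmoothTrack: %d positions, lowess f = %g\n",
              length(object@positions), object@spanF))
})

setMethod("show", "PeakSet", function(object) {
  p <- object@peaks
  cat(sprintf("PeakSet: %d peaks (min prominence %g, min separation %g bp)\n",
              nrow(p), object@minProminence, object@minSeparation))
  if (nrow(p)) {
    lab <- ifelse(p$label > 0, paste0("+", p$label), as.character(p$label))
    cat(sprintf("  %s at %s bp\n", paste(lab, collapse = ", "),
                paste(round(p$center), collapse = ", ")))
  }
})

setMethod("show", "FragmentSizeModel", function(object) {
  cat(sprintf(paste0(
    "FragmentSizeModel: mono %g-%g bp, di %g-%g bp (mono ref %g bp)\n",
    "  linker %g-%g bp, expected peak-to-peak spacing %g-%g bp, footprint %g bp\n"),
    object@monoRange[1], object@monoRange[2], object@diRange[1], object@diRange[2],
    object@monoRef, object@linkerRange[1], object@linkerRange[2],
    object@spacingRange[1], object@spacingRange[2], object@footprint))
})

setMethod("show", "NdrCall", function(object) {
  if (isTRUE(object@called))
    cat(sprintf("NdrCall: -1/+1 separation %g bp - footprint %g bp = NDR width %g bp\n",
                object@separation, object@footprint, object@width))
  else
    cat(sprintf("NdrCall: no call (%s)\n", object@reason))
})

setMethod("show", "WilcoxonTrack", function(object) {
  ok <- !is.na(object@pValue)
  cat(sprintf("WilcoxonTrack: %d windows (%d tested), %d significant at alpha = %g\n",
              length(object@windowCenters), sum(ok),
              sum(object@significant), object@alpha))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d genes (%d minus-strand) on a %g bp genome\n",
    "  %d cells, wrap %g bp (sd %g), probes %g bp every %g bp, seed %d\n"),
    nrow(object@genes), sum(object@genes$strand == "-"), object@genomeLength,
    object@nCells, object@wrapLength, object@fragmentLengthSd,
    object@probeLength, object@probeStep, object@seed))
  for (nm in names(object@groupTemplates))
    cat(sprintf("  group '%s': templates at %s bp\n", nm,
                paste(object@groupTemplates[[nm]]$rel_center, collapse = ", ")))
})
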