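#' @rdname WindowTrack-class
#' @param x a track-like object.
#' @export
setGeneric("windowCenters", function(x) standardGeneric("windowCenters"))

#' @rdname WindowTrack-class
#' @export
setGeneric("meanSignal", function(x) standardGeneric("meanSignal"))

#' @rdname WindowTrack-class
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname SmoothTrack-class
#' @param x a `SmoothTrack`.
#' @export
setGeneric("trackPositions", function(x) standardGeneric("trackPositions"))

#' @rdname SmoothTrack-class
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname PeakSet-class
#' @param x a `PeakSet`.
#' @export
setGeneric("peaksTable", function(x) standardGeneric("peaksTable"))

#' @rdname FragmentSizeModel-class
#' @param x a `FragmentSizeModel`.
#' @export
setGeneric("linkerRange", function(x) standardGeneric("linkerRange"))

#' @rdname FragmentSizeModel-class
#' @export
setGeneric("spacingRange", function(x) standardGeneric("spacingRange"))

#' @rdname FragmentSizeModel-class
#' @export
setGeneric("footprint", function(x) standardGeneric("footprint"))

#' @rdname WilcoxonTrack-class
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname WilcoxonTrack-class
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))
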