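## Peak calling on smoothed aggregate profiles, nucleosome labeling,
## spacings, NDR sizing and -1/+1 occupancy ratios, plus the gel-band
## fragment-size arithmetic that predicts the expected nucleosome repeat.

#' Gel-derived fragment-size arithmetic
#'
#' From the mono- and di-nucleosome band sizes read off an MNase digestion
#' gel, derives the linker-length range
#' `[di_low - 2*mono_ref, di_high - 2*mono_ref]` and the expected
#' peak-to-peak nucleosome spacing `mono_ref + linker`.  With the default
#' bands (mono 150-175 bp, di 320-360 bp, reference 150 bp) this gives a
#' 20-60 bp linker and a 170-210 bp expected repeat.
#'
#' @param monoRange mono-nucleosome band `[low, high]` in bp.
#' @param diRange di-nucleosome band `[low, high]` in bp.
#' @param monoRef reference mono-nucleosome length in bp; the band's lower
#'   edge reproduces both derived ranges above.
#' @param footprint nucleosome footprint used downstream for NDR sizing
#'   (default 160 bp, inside the observed mono band).
#' @return a [FragmentSizeModel-class].
#' @examples
#' fragmentSizeModel()             # linker 20-60, spacing 170-210
#' @export
fragmentSizeModel <- function(monoRange = c(150, 175), diRange = c(320, 360),
                              monoRef = 150, footprint = 160) {
  if (monoRange[1] > monoRange[2] || diRange[1] > diRange[2])
    stop("band ranges must be ordered [low, high]", call. = FALSE)
  if (diRange[1] < 2 * monoRef)
    stop("di-band low edge below twice the mono reference (negative linker)",
         call. = FALSE)
  linker <- diRange - 2 * monoRef
  new("FragmentSizeModel", monoRange = as.numeric(monoRange),
      diRange = as.numeric(diRange), monoRef = as.numeric(monoRef),
      footprint = as.numeric(footprint), linkerRange = as.numeric(linker),
      spacingRange = as.numeric(monoRef + linker))
}

# Local maxima of y: strictly greater than both neighbors; plateaus take
# the centroid of the run.  Track ends are never peaks.
.localMaxima <- function(x, y) {
  n <- length(y)
  if (n < 3) return(data.frame(center = numeric(), amplitude = numeric(),
                               index = integer()))
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (k == 1L || k == length(r$values)) next        # touches a track end
    if (r$values[k] > r$values[k - 1L] && r$values[k] > r$values[k + 1L]) {
      i1 <- starts[k]; i2 <- ends[k]
      out[[length(out) + 1L]] <- data.frame(
        center = mean(x[i1:i2]), amplitude = r$values[k],
        index = as.integer(round((i1 + i2) / 2)))
    }
  }
  if (!length(out)) return(data.frame(center = numeric(),
                                      amplitude = numeric(), index = integer()))
  do.call(rbind, out)
}

# Topographic prominence: height minus the higher of the two bases, where
# each base is the minimum between the peak and the nearest higher point
# on that side (track end if no higher point exists).
.prominence <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    left <- if (i > 1) {
      seg <- y[(i - 1):1]
      stopAt <- which(seg > h)[1]
      if (is.na(stopAt)) min(seg) else min(seg[seq_len(stopAt)])
    } else h
    right <- if (i < length(y)) {
      seg <- y[(i + 1):length(y)]
      stopAt <- which(seg > h)[1]
      if (is.na(stopAt)) min(seg) else min(seg[seq_len(stopAt)])
    } else h
    h - max(left, right)
  }, numeric(1))
}

#' Call nucleosome peaks on a smoothed profile
#'
#' Finds local maxima (plateaus take their centroid; track ends are never
#' peaks), computes their topographic prominence, greedily retains peaks
#' in decreasing prominence order subject to a minimum center-to-center
#' separation, and labels the survivors with [labelPeaks()].  The default
#' 100 bp separation suppresses shoulder artifacts while staying well
#' below the expected 170-210 bp nucleosome repeat.
#'
#' @param track a [SmoothTrack-class] (at least 3 points).
#' @param minProminence minimum prominence in log2 units (default 0.05).
#' @param minSeparation minimum spacing between retained peaks in bp
#'   (default 100).
#' @return a [PeakSet-class]; empty if no peak qualifies.
#' @export
callPeaks <- function(track, minProminence = 0.05, minSeparation = 100) {
  stopifnot(is(track, "SmoothTrack"))
  x <- track@positions; y <- track@value
  if (length(x) < 3) stop("track needs at least 3 points", call. = FALSE)
  cand <- .localMaxima(x, y)
  if (nrow(cand)) {
    cand$prominence <- .prominence(y, cand$index)
    cand <- cand[cand$prominence >= minProminence, , drop = FALSE]
  }
  keep <- integer()
  if (nrow(cand)) {
    ord <- order(-cand$prominence, -cand$amplitude, cand$center)
    for (i in ord)
      if (!length(keep) || all(abs(cand$center[keep] - cand$center[i]) >= minSeparation))
        keep <- c(keep, i)
  }
  sel <- if (length(keep)) {
    s <- cand[sort(keep), c("center", "amplitude", "prominence"), drop = FALSE]
    s[order(s$center), , drop = FALSE]
  } else {
    data.frame(center = numeric(), amplitude = numeric(),
               prominence = numeric())
  }
  sel <- data.frame(label = labelPeaks(sel$center), sel, row.names = NULL)
  new("PeakSet", peaks = sel, minProminence = minProminence,
      minSeparation = minSeparation)
}

#' Label nucleosome peaks relative to the TSS
#'
#' Peaks at or downstream of the TSS (center >= 0) are labeled +1, +2, ...
#' outward; upstream peaks are -1, -2, ... outward.  A peak at exactly 0
#' is +1.
#'
#' @param x a numeric vector of peak centers (sorted ascending), or a
#'   [PeakSet-class] to relabel.
#' @return integer labels (for a numeric `x`) or the relabeled `PeakSet`.
#' @examples
#' labelPeaks(c(-450, -290, -170, 115, 250))   # -3 -2 -1  1  2
#' @export
labelPeaks <- function(x) {
  if (is(x, "PeakSet")) {
    p <- x@peaks
    p$label <- labelPeaks(p$center)
    x@peaks <- p
    validObject(x)
    return(x)
  }
  centers <- x
  if (is.unsorted(centers, strictly = TRUE))
    stop("peak centers must be sorted and distinct", call. = FALSE)
  labels <- integer(length(centers))
  up <- centers < 0
  labels[up] <- -rev(seq_len(sum(up)))
  labels[!up] <- seq_len(sum(!up))
  labels
}

#' Successive peak-to-peak spacings
#'
#' @param peaks a [PeakSet-class].
#' @return numeric vector of successive center differences (bp), empty
#'   with fewer than two peaks.
#' @export
peakSpacings <- function(peaks) {
  stopifnot(is(peaks, "PeakSet"))
  if (nrow(peaks@peaks) < 2) return(numeric())
  diff(peaks@peaks$center)
}

.peakRow <- function(peaks, label) {
  p <- peaks@peaks
  p[match(label, p$label), , drop = FALSE]
}

#' Nucleosome-depleted-region width
#'
#' Sizes the NDR as the -1/+1 peak separation minus one nucleosome
#' footprint: a 290 bp separation with the default 160 bp footprint gives
#' a 130 bp NDR.
#'
#' @param peaks a [PeakSet-class] containing labels -1 and +1.
#' @param model a [FragmentSizeModel-class] supplying the footprint.
#' @return an [NdrCall-class]; a no-call (with reason) when either
#'   flanking peak is missing.
#' @export
ndrWidth <- function(peaks, model = fragmentSizeModel()) {
  stopifnot(is(peaks, "PeakSet"), is(model, "FragmentSizeModel"))
  m1 <- .peakRow(peaks, -1L); p1 <- .peakRow(peaks, 1L)
  miss <- c(if (is.na(m1$center)) "-1", if (is.na(p1$center)) "+1")
  if (length(miss))
    return(new("NdrCall", called = FALSE, separation = NA_real_,
               width = NA_real_, footprint = model@footprint,
               reason = sprintf("missing flanking peak(s): %s",
                                paste(miss, collapse = ", "))))
  sep <- p1$center - m1$center
  new("NdrCall", called = TRUE, separation = sep,
      width = sep - model@footprint, footprint = model@footprint,
      reason = "")
}

#' -1/+1 occupancy ratio and its change between samples
#'
#' The occupancy ratio is the nucleosome density at the -1 peak divided
#' by the density at the +1 peak.  Peak amplitudes are log2(MNase/gDNA)
#' values, so on the default `"linear"` scale the density ratio is
#' `2^(amplitude(-1) - amplitude(+1))`; this is the scale on which a
#' halving of -1 occupancy halves the ratio.  `scale = "log2"` instead
#' returns the literal quotient of the two log2 amplitudes (meaningful
#' only when both are positive).  The percent reduction relative to a
#' reference sample is `(1 - ratio/reference) * 100`.
#'
#' @param peaks a [PeakSet-class] with -1 and +1 called.
#' @param scale `"linear"` (default) or `"log2"`, see above.
#' @return `occupancyRatio`: the ratio (`NA` with a warning when either
#'   peak is missing, or for `"log2"` when the +1 amplitude is zero).
#' @export
occupancyRatio <- function(peaks, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is(peaks, "PeakSet"))
  m1 <- .peakRow(peaks, -1L); p1 <- .peakRow(peaks, 1L)
  if (is.na(m1$center) || is.na(p1$center)) {
    warning("occupancy ratio needs both -1 and +1 peaks", call. = FALSE)
    return(NA_real_)
  }
  if (scale == "linear") return(2^(m1$amplitude - p1$amplitude))
  if (!is.finite(p1$amplitude) || p1$amplitude == 0) {
    warning("+1 amplitude is zero; ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  m1$amplitude / p1$amplitude
}

#' @rdname occupancyRatio
#' @param ratio,referenceRatio occupancy ratios of the sample of interest
#'   and of the reference sample (`referenceRatio > 0`).
#' @return `percentReduction`: the reduction in percent (positive when
#'   the ratio dropped relative to the reference).
#' @examples
#' percentReduction(0.65, 1.0)   # 35
#' @export
percentReduction <- function(ratio, referenceRatio) {
  if (!is.finite(referenceRatio) || referenceRatio <= 0)
    stop("referenceRatio must be positive", call. = FALSE)
  (1 - ratio / referenceRatio) * 100
}

#' Write a peak table as TSV
#'
#' @param peaks a [PeakSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(peaks, path) {
  stopifnot(is(peaks, "PeakSet"))
  write.table(peaks@peaks, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
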