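## Central S4 containers.  Probes and TSS annotations are plain GRanges
## (1-based internally, converted at the file boundary); signal tables are
## validated data.frames.  The classes below hold derived objects whose
## invariants are worth enforcing.

#' WindowTrack: sliding-window aggregate nucleosome-density profile
#'
#' The aggregate profile before smoothing: per window center (default a
#' 30 bp window advanced in 10 bp steps across -600..+600 bp around the
#' TSS) the mean probe log2(MNase/gDNA) ratio and the number of pooled
#' (gene, probe) observations.  `meanSignal` is `NA` exactly where
#' `nPoints` is zero (probe gaps, e.g. repeat-masked stretches).
#'
#' @slot windowCenters numeric, strictly increasing, constant step (bp).
#' @slot meanSignal numeric, mean log2 ratio per window (`NA` if empty).
#' @slot nPoints integer, observations pooled per window.
#' @slot windowWidth numeric, window width in bp.
#' @slot step numeric, step between window centers in bp.
#'
#' @seealso [aggregateWindows()], [smoothLowess()]
#' @export
setClass("WindowTrack",
  representation(
    windowCenters = "numeric",
    meanSignal    = "numeric",
    nPoints       = "integer",
    windowWidth   = "numeric",
    step          = "numeric"
  )
)

setValidity("WindowTrack", function(object) {
  msg <- character()
  n <- length(object@windowCenters)
  if (length(object@meanSignal) != n || length(object@nPoints) != n)
    msg <- c(msg, "windowCenters, meanSignal and nPoints must have equal length")
  if (n >= 2) {
    d <- diff(object@windowCenters)
    if (any(d <= 0)) msg <- c(msg, "windowCenters must be strictly increasing")
    if (max(d) - min(d) > 1e-8) msg <- c(msg, "windowCenters must have a constant step")
  }
  if (any(object@nPoints < 0, na.rm = TRUE)) msg <- c(msg, "nPoints must be >= 0")
  bad <- xor(is.na(object@meanSignal), object@nPoints == 0L)
  if (length(bad) && any(bad))
    msg <- c(msg, "meanSignal must be NA exactly where nPoints is 0")
  if (length(msg)) msg else TRUE
})

#' SmoothTrack: lowess-smoothed aggregate profile
#'
#' Locally weighted regression (tricube weights, robustifying iterations)
#' of a [WindowTrack], evaluated at the non-missing window centers only:
#' probe gaps are never imputed.
#'
#' @slot positions numeric bp, the non-missing window centers.
#' @slot value numeric, smoothed log2 ratio per position.
#' @slot spanF numeric in (0, 1], the lowess smoother span `f`.
#'
#' @seealso [smoothLowess()], [callPeaks()]
#' @export
setClass("SmoothTrack",
  representation(
    positions = "numeric",
    value     = "numeric",
    spanF     = "numeric"
  )
)

setValidity("SmoothTrack", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@value))
    msg <- c(msg, "positions and value must have equal length")
  if (is.unsorted(object@positions, strictly = TRUE))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@spanF) != 1 || object@spanF <= 0 || object@spanF > 1)
    msg <- c(msg, "spanF must be a single value in (0, 1]")
  if (anyNA(object@value)) msg <- c(msg, "value must be finite")
  if (length(msg)) msg else TRUE
})

#' PeakSet: called and labeled nucleosome peaks
#'
#' Local maxima of a smoothed aggregate profile, retained greedily in
#' decreasing prominence order subject to a minimum separation, then
#' labeled -n..-1 upstream and +1..+n downstream of the TSS (a peak at
#' exactly 0 is +1).  Amplitude is the smoothed profile value at the peak
#' center, matching the "density at" a nucleosome reading of the profile.
#'
#' @slot peaks data.frame with columns `label` (integer, no 0), `center`
#'   (bp relative to TSS), `amplitude`, `prominence`; ordered by center.
#' @slot minProminence numeric, caller parameter.
#' @slot minSeparation numeric bp, caller parameter.
#'
#' @seealso [callPeaks()], [peakSpacings()], [ndrWidth()], [occupancyRatio()]
#' @export
setClass("PeakSet",
  representation(
    peaks         = "data.frame",
    minProminence = "numeric",
    minSeparation = "numeric"
  )
)

setValidity("PeakSet", function(object) {
  msg <- character()
  p <- object@peaks
  need <- c("label", "center", "amplitude", "prominence")
  if (!all(need %in% names(p)))
    return(sprintf("peaks must have columns %s", paste(need, collapse = ", ")))
  if (nrow(p)) {
    if (is.unsorted(p$center, strictly = TRUE))
      msg <- c(msg, "peak centers must be strictly increasing")
    if (anyDuplicated(p$label)) msg <- c(msg, "peak labels must be unique")
    if (any(p$label == 0)) msg <- c(msg, "peak label 0 is not allowed")
    if (any(p$label < 0 & p$center >= 0) || any(p$label > 0 & p$center < 0))
      msg <- c(msg, "negative labels require center < 0, positive labels center >= 0")
    if (nrow(p) >= 2 && length(object@minSeparation) == 1 &&
        any(diff(p$center) < object@minSeparation - 1e-8))
      msg <- c(msg, "successive peak centers closer than minSeparation")
  }
  if (length(msg)) msg else TRUE
})

#' FragmentSizeModel: gel-derived nucleosome fragment-size arithmetic
#'
#' From the gel-estimated mono- and di-nucleosome band sizes the model
#' derives the linker-length range (di-band minus two reference mono
#' lengths) and the expected peak-to-peak nucleosome spacing (mono
#' reference plus linker).  The nucleosome footprint used for NDR sizing
#' is carried alongside.
#'
#' @slot monoRange numeric length-2, mono-nucleosome band (bp).
#' @slot diRange numeric length-2, di-nucleosome band (bp).
#' @slot monoRef numeric, reference mono-nucleosome length (bp).
#' @slot footprint numeric, nucleosome footprint used for NDR width (bp).
#' @slot linkerRange numeric length-2, derived linker range (bp).
#' @slot spacingRange numeric length-2, derived peak-to-peak spacing (bp).
#'
#' @seealso [fragmentSizeModel()], [ndrWidth()]
#' @export
setClass("FragmentSizeModel",
  representation(
    monoRange    = "numeric",
    diRange      = "numeric",
    monoRef      = "numeric",
    footprint    = "numeric",
    linkerRange  = "numeric",
    spacingRange = "numeric"
  )
)

setValidity("FragmentSizeModel", function(object) {
  msg <- character()
  for (nm in c("monoRange", "diRange", "linkerRange", "spacingRange")) {
    v <- slot(object, nm)
    if (length(v) != 2 || v[1] > v[2])
      msg <- c(msg, sprintf("%s must be an ordered [low, high] pair", nm))
  }
  if (object@diRange[1] < 2 * object@monoRef)
    msg <- c(msg, "di-band low edge below twice the mono reference (negative linker)")
  if (!isTRUE(all.equal(object@linkerRange, object@diRange - 2 * object@monoRef)))
    msg <- c(msg, "linkerRange must equal diRange - 2*monoRef")
  if (!isTRUE(all.equal(object@spacingRange, object@monoRef + object@linkerRange)))
    msg <- c(msg, "spacingRange must equal monoRef + linkerRange")
  if (length(msg)) msg else TRUE
})

#' NdrCall: nucleosome-depleted-region width between -1 and +1 peaks
#'
#' The NDR is sized as the -1/+1 center-to-center separation minus one
#' nucleosome footprint.  When either flanking peak is missing the call
#' carries `called = FALSE` and a reason instead of numbers.
#'
#' @slot called logical, whether both flanking peaks were available.
#' @slot separation numeric bp, center(+1) - center(-1) (`NA` if no call).
#' @slot width numeric bp, separation - footprint (`NA` if no call).
#' @slot footprint numeric bp, the footprint used.
#' @slot reason character, why the call failed (empty string on success).
#'
#' @seealso [ndrWidth()]
#' @export
setClass("NdrCall",
  representation(
    called     = "logical",
    separation = "numeric",
    width      = "numeric",
    footprint  = "numeric",
    reason     = "character"
  )
)

setValidity("NdrCall", function(object) {
  if (isTRUE(object@called) &&
      !isTRUE(all.equal(object@width, object@separation - object@footprint)))
    return("width must equal separation - footprint")
  TRUE
})

#' WilcoxonTrack: per-window two-group rank-sum comparison
#'
#' For each window center, the two-sided unpaired Wilcoxon rank-sum
#' p-value comparing per-gene window means between two gene groups, with
#' the significance mask at `alpha`.  Windows where either group has
#' fewer than two observations carry `NA` p-values and are never
#' significant.
#'
#' @slot windowCenters numeric bp.
#' @slot pValue numeric in (0, 1] or `NA` per window.
#' @slot significant logical per window.
#' @slot alpha numeric, significance threshold.
#' @slot nA,nB integer, non-missing observations per group per window.
#'
#' @seealso [wilcoxonTrack()]
#' @export
setClass("WilcoxonTrack",
  representation(
    windowCenters = "numeric",
    pValue        = "numeric",
    significant   = "logical",
    alpha         = "numeric",
    nA            = "integer",
    nB            = "integer"
  )
)

setValidity("WilcoxonTrack", function(object) {
  msg <- character()
  n <- length(object@windowCenters)
  if (!all(lengths(list(object@pValue, object@significant, object@nA, object@nB)) == n))
    msg <- c(msg, "all per-window slots must have equal length")
  sig <- !is.na(object@pValue) & object@pValue < object@alpha
  if (length(object@significant) == n && !identical(sig, object@significant))
    msg <- c(msg, "significant must be pValue < alpha (FALSE where pValue is NA)")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: generative description of a synthetic MNase-chip run
#'
#' Fully specifies a synthetic experiment: a linear genome tiled with
#' 50 bp probes every 20 bp, genes with strand-aware TSSs assigned to
#' groups, per-group nucleosome templates (TSS-relative center, occupancy
#' = probability a cell carries the nucleosome, fuzziness = sd of
#' per-cell positional jitter), a cell population size, MNase protection
#' (fragment length around the ~147 bp wrap), uniform free-DNA
#' background, a uniform gDNA control channel, and multiplicative
#' log-normal intensity noise.  Given the same seed the generated tables
#' are identical.
#'
#' @slot genomeLength numeric bp.
#' @slot genes data.frame with columns `gene_id`, `tss` (0-based bp),
#'   `strand` ("+"/"-"), `group`.
#' @slot groupTemplates named list; per group a data.frame with columns
#'   `rel_center` (bp), `occupancy` in \[0,1\], `fuzziness` (bp, sd).
#' @slot nCells integer, cells in the simulated population.
#' @slot wrapLength numeric bp, mean protected-fragment length.
#' @slot fragmentLengthSd numeric bp.
#' @slot probeLength,probeStep numeric bp, array design.
#' @slot backgroundRate numeric, free-DNA coverage per bp per cell.
#' @slot gdnaCoverage numeric, gDNA-channel coverage per bp per cell.
#' @slot channelNoiseSd,gdnaNoiseSd numeric, sd of log-normal noise
#'   (on the natural-log scale) for the MNase and gDNA channels.
#' @slot seed integer.
#'
#' @seealso [simulateExperiment()], [makeStageConfig()]
#' @export
setClass("SimulationConfig",
  representation(
    genomeLength     = "numeric",
    genes            = "data.frame",
    groupTemplates   = "list",
    nCells           = "integer",
    wrapLength       = "numeric",
    fragmentLengthSd = "numeric",
    probeLength      = "numeric",
    probeStep        = "numeric",
    backgroundRate   = "numeric",
    gdnaCoverage     = "numeric",
    channelNoiseSd   = "numeric",
    gdnaNoiseSd      = "numeric",
    seed             = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  g <- object@genes
  if (!all(c("gene_id", "tss", "strand", "group") %in% names(g)))
    return("genes must have columns gene_id, tss, strand, group")
  if (anyDuplicated(g$gene_id)) msg <- c(msg, "gene_id must be unique")
  if (!all(g$strand %in% c("+", "-"))) msg <- c(msg, "strand must be '+' or '-'")
  if (!all(g$group %in% names(object@groupTemplates)))
    msg <- c(msg, "every gene group needs an entry in groupTemplates")
  for (nm in names(object@groupTemplates)) {
    tpl <- object@groupTemplates[[nm]]
    if (!all(c("rel_center", "occupancy", "fuzziness") %in% names(tpl))) {
      msg <- c(msg, sprintf("templates for group '%s' need rel_center, occupancy, fuzziness", nm))
      next
    }
    if (any(tpl$occupancy < 0 | tpl$occupancy > 1))
      msg <- c(msg, sprintf("occupancy outside [0,1] in group '%s'", nm))
    if (any(tpl$fuzziness < 0))
      msg <- c(msg, sprintf("negative fuzziness in group '%s'", nm))
  }
  if (object@probeStep > object@probeLength)
    msg <- c(msg, "probeStep must be <= probeLength")
  if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
  if (any(c(object@backgroundRate, object@gdnaCoverage,
            object@channelNoiseSd, object@gdnaNoiseSd) < 0))
    msg <- c(msg, "rates and noise sds must be >= 0")
  if (length(msg)) msg else TRUE
})
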