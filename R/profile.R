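## From two-channel probe intensities to TSS-anchored aggregate profiles:
## log2 ratio -> replicate mean -> strand-adjusted TSS-relative mapping ->
## 30/10 sliding-window aggregation -> lowess smoothing.

#' Per-probe log2(MNase/gDNA) ratios
#'
#' Computes `log2(mnase / gdna)` for every (probe, replicate, sample) row.
#' Channel normalization is assumed to have happened upstream; optionally
#' the per-(replicate, sample) median log2 ratio can be subtracted to
#' center each array at zero.
#'
#' @param table validated two-channel signal table
#'   (see [readSignalTable()]).
#' @param medianCenter logical; subtract the per-array median log2 ratio
#'   (default `FALSE`).
#' @return the table with a `log2_ratio` column appended.
#' @examples
#' tab <- data.frame(probe_id = c("p1", "p2"), mnase = c(800, 300),
#'                   gdna = c(400, 1200), replicate_id = "r1", sample_id = "s1")
#' computeLog2Ratio(tab)$log2_ratio   # 1, -2
#' @export
computeLog2Ratio <- function(table, medianCenter = FALSE) {
  table <- validateSignalTable(table)
  table$log2_ratio <- log2(table$mnase / table$gdna)
  if (medianCenter) {
    key <- interaction(table$replicate_id, table$sample_id, drop = TRUE)
    med <- tapply(table$log2_ratio, key, stats::median)
    table$log2_ratio <- table$log2_ratio - as.numeric(med[as.character(key)])
  }
  table
}

#' Average log2 ratios across replicates
#'
#' The mean signal across replicates of a sample is assigned to each
#' probe.  Probes covered by only one replicate keep their single value;
#' a warning reports how many such probes there were.
#'
#' @param ratios data.frame with columns `probe_id`, `sample_id`,
#'   `replicate_id`, `log2_ratio` (from [computeLog2Ratio()]).
#' @return data.frame `probe_id`, `sample_id`, `log2_ratio`,
#'   `n_replicates`.
#' @export
averageReplicates <- function(ratios) {
  need <- c("probe_id", "sample_id", "replicate_id", "log2_ratio")
  if (!all(need %in% names(ratios)))
    stop("ratios needs columns ", paste(need, collapse = ", "), call. = FALSE)
  nrep <- length(unique(ratios$replicate_id))
  key <- interaction(ratios$probe_id, ratios$sample_id, drop = TRUE)
  agg <- data.frame(
    probe_id = as.character(tapply(ratios$probe_id, key, `[`, 1)),
    sample_id = as.character(tapply(ratios$sample_id, key, `[`, 1)),
    log2_ratio = as.numeric(tapply(ratios$log2_ratio, key, mean)),
    n_replicates = as.integer(tapply(ratios$log2_ratio, key, length)),
    row.names = NULL)
  short <- sum(agg$n_replicates < nrep)
  if (short > 0)
    warning(sprintf("%d probe/sample pairs covered by fewer than %d replicates; %s",
                    short, nrep, "mean taken over available replicates"),
            call. = FALSE)
  agg
}

#' Replicate concordance (r squared)
#'
#' Squared Pearson correlation of per-probe log2 ratios between two
#' replicates, over their common probes.
#'
#' @param rep1,rep2 named numeric vectors of per-probe values (names are
#'   probe ids).
#' @return r^2 in \[0, 1\], or `NA` if either replicate has zero variance.
#' @export
replicateConcordance <- function(rep1, rep2) {
  common <- intersect(names(rep1), names(rep2))
  if (length(common) < 3)
    stop("need >= 3 common probes to assess concordance", call. = FALSE)
  x <- rep1[common]; y <- rep2[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in a replicate; concordance undefined", call. = FALSE)
    return(NA_real_)
  }
  unname(stats::cor(x, y)^2)
}

#' Place probe signals on strand-adjusted TSS-relative coordinates
#'
#' For every gene, every probe on the same chromosome whose center falls
#' within `flank` bp of the TSS contributes one record at offset
#' `center - tss` (plus strand) or `tss - center` (minus strand), so that
#' negative positions are always upstream of transcription.  A probe may
#' contribute to several genes.
#'
#' @param probes probe `GRanges` from [readProbes()].
#' @param signal named numeric vector of per-probe values (names are
#'   probe ids), e.g. replicate-averaged log2 ratios.
#' @param tss TSS `GRanges` from [readTss()].
#' @param flank maximum |offset| in bp (default 600; offsets at exactly
#'   `flank` are kept).
#' @return data.frame `gene_id`, `probe_id`, `rel_pos`, `log2_ratio`.
#' @export
mapProbesToTss <- function(probes, signal, tss, flank = 600) {
  ids <- mcols(probes)$probe_id
  keep <- ids %in% names(signal)
  probes <- probes[keep]
  ids <- ids[keep]
  centers <- probeCenters(probes)
  pchrom <- as.character(seqnames(probes))
  vals <- as.numeric(signal[ids])
  out <- vector("list", length(tss))
  genes <- mcols(tss)$gene_id
  tss0 <- mcols(tss)$tss
  gchrom <- as.character(seqnames(tss))
  gstr <- as.character(strand(tss))
  for (i in seq_along(tss)) {
    on <- pchrom == gchrom[i]
    rel <- if (gstr[i] == "+") centers[on] - tss0[i] else tss0[i] - centers[on]
    inr <- abs(rel) <= flank
    if (!any(inr)) {
      warning(sprintf("gene '%s' has no probe within %g bp of its TSS",
                      genes[i], flank), call. = FALSE)
      next
    }
    out[[i]] <- data.frame(gene_id = genes[i],
                           probe_id = ids[on][inr],
                           rel_pos = rel[inr],
                           log2_ratio = vals[on][inr])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), probe_id = character(),
                      rel_pos = numeric(), log2_ratio = numeric())
  rownames(res) <- NULL
  res
}

# Window centers for a flank/step grid: -flank, -flank+step, ..., +flank.
.windowGrid <- function(flank, step) seq(-flank, flank, by = step)

# Mean and count of `values` per half-open window [c - w/2, c + w/2).
# Windows overlap when width > step, so a record can land in several.
.windowStats <- function(pos, values, centers, width) {
  half <- width / 2
  n <- integer(length(centers))
  s <- numeric(length(centers))
  for (k in seq_along(centers)) {
    inw <- pos >= centers[k] - half & pos < centers[k] + half
    n[k] <- sum(inw)
    if (n[k]) s[k] <- sum(values[inw])
  }
  list(mean = ifelse(n > 0, s / pmax(n, 1L), NA_real_), n = n)
}

#' Aggregate TSS-relative signals with a sliding window
#'
#' Tallies the signals of a gene set with a sliding window (default 30 bp
#' wide, advanced in 10 bp steps across -flank..+flank).  Window
#' membership is half-open, `[c - width/2, c + width/2)`.  By default all
#' (gene, probe) records are pooled with equal weight; with
#' `perGeneMean = TRUE` each gene contributes its within-window mean once
#' and `nPoints` counts contributing genes.
#'
#' @param signals data.frame from [mapProbesToTss()].
#' @param genes character vector of gene ids to aggregate (non-empty).
#' @param width,step,flank window geometry in bp (defaults 30, 10, 600).
#' @param perGeneMean logical, see above (default `FALSE`).
#' @return a [WindowTrack-class].
#' @export
aggregateWindows <- function(signals, genes, width = 30, step = 10,
                             flank = 600, perGeneMean = FALSE) {
  if (length(genes) == 0) stop("empty gene set", call. = FALSE)
  if (width < step) stop("width must be >= step", call. = FALSE)
  sel <- signals[signals$gene_id %in% genes, , drop = FALSE]
  centers <- .windowGrid(flank, step)
  if (perGeneMean) {
    m <- perGeneWindowMatrix(signals, genes, width = width, step = step,
                             flank = flank)
    n <- as.integer(colSums(!is.na(m)))
    mu <- ifelse(n > 0, colMeans(m, na.rm = TRUE), NA_real_)
    return(new("WindowTrack", windowCenters = centers, meanSignal = mu,
               nPoints = n, windowWidth = width, step = step))
  }
  st <- .windowStats(sel$rel_pos, sel$log2_ratio, centers, width)
  new("WindowTrack", windowCenters = centers, meanSignal = st$mean,
      nPoints = st$n, windowWidth = width, step = step)
}

#' Lowess-smooth a window track
#'
#' Locally weighted linear regression (tricube weights with robustifying
#' iterations, span a fraction `spanF` of the points, default 0.05)
#' fitted through the non-missing window means and evaluated at their
#' centers.  Missing windows are excluded, never imputed.
#'
#' @param track a [WindowTrack-class].
#' @param spanF smoother span in (0, 1] (default 0.05).
#' @param iterations robustifying iterations (default 3).
#' @return a [SmoothTrack-class].
#' @export
smoothLowess <- function(track, spanF = 0.05, iterations = 3) {
  stopifnot(is(track, "WindowTrack"))
  keep <- !is.na(track@meanSignal)
  x <- track@windowCenters[keep]
  y <- track@meanSignal[keep]
  if (length(x) < max(3, ceiling(spanF * length(x))))
    stop("too few non-missing windows to smooth; consider a larger span",
         call. = FALSE)
  fit <- lowess(x, y, f = spanF, iter = iterations)
  new("SmoothTrack", positions = fit$x, value = fit$y, spanF = spanF)
}
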