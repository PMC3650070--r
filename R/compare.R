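## Position-by-position comparison of gene groups.  The observation unit
## is the per-gene window mean, so each window compares e.g. 6 expressed
## against 31 non-expressed genes with a two-sided unpaired Wilcoxon
## rank-sum test.

#' Per-gene sliding-window signal matrix
#'
#' Entry (g, c) is the mean log2 ratio of gene g's probes inside window c
#' (same half-open 30/10 window geometry as [aggregateWindows()]); `NA`
#' where the gene has no probe in the window.
#'
#' @inheritParams aggregateWindows
#' @return numeric matrix, genes x window centers (dimnames set).
#' @export
perGeneWindowMatrix <- function(signals, genes, width = 30, step = 10,
                                flank = 600) {
  if (length(genes) == 0) stop("empty gene set", call. = FALSE)
  centers <- .windowGrid(flank, step)
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(centers),
              dimnames = list(genes, centers))
  attr(m, "nPoints") <- matrix(0L, nrow = length(genes), ncol = length(centers),
                               dimnames = list(genes, centers))
  for (g in genes) {
    sel <- signals[signals$gene_id == g, , drop = FALSE]
    if (!nrow(sel)) next
    st <- .windowStats(sel$rel_pos, sel$log2_ratio, centers, width)
    m[g, ] <- st$mean
    attr(m, "nPoints")[g, ] <- st$n
  }
  m
}

# Two-sided unpaired rank-sum p-value; exact enumeration when both sizes
# are <= exactMax and the pooled sample is tie-free, otherwise the normal
# approximation with midranks, tie-corrected variance and continuity
# correction (what wilcox.test does under the same switches).
.ranksumP <- function(a, b, exactMax = 8) {
  exact <- length(a) <= exactMax && length(b) <= exactMax &&
    !anyDuplicated(c(a, b))
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
}

#' Window-by-window Wilcoxon rank-sum comparison of two groups
#'
#' For every window center, compares the per-gene window means of group A
#' against group B with a two-sided unpaired Wilcoxon rank-sum test.
#' Exact enumeration is used when both groups have at most `exactMax`
#' non-missing values and no ties; otherwise the normal approximation
#' with tie correction and continuity correction.  Windows where either
#' group has fewer than two values get an `NA` p-value.  Raw p-values are
#' compared with `alpha` (no multiple-testing correction, matching the
#' classic green significance mask); set `adjust = "BH"` for a
#' Benjamini-Hochberg-adjusted mask instead.
#'
#' @param matrixA,matrixB per-gene window matrices from
#'   [perGeneWindowMatrix()] with identical window grids.
#' @param alpha significance threshold (default 0.05).
#' @param exactMax largest group size for the exact branch (default 8).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a [WilcoxonTrack-class].
#' @export
wilcoxonTrack <- function(matrixA, matrixB, alpha = 0.05, exactMax = 8,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (ncol(matrixA) != ncol(matrixB) ||
      !isTRUE(all.equal(colnames(matrixA), colnames(matrixB))))
    stop("the two matrices must share one window grid", call. = FALSE)
  centers <- as.numeric(colnames(matrixA))
  nA <- as.integer(colSums(!is.na(matrixA)))
  nB <- as.integer(colSums(!is.na(matrixB)))
  p <- rep(NA_real_, length(centers))
  for (k in seq_along(centers)) {
    if (nA[k] < 2 || nB[k] < 2) next
    a <- matrixA[, k]; b <- matrixB[, k]
    p[k] <- .ranksumP(a[!is.na(a)], b[!is.na(b)], exactMax = exactMax)
  }
  pMask <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
  new("WilcoxonTrack", windowCenters = centers, pValue = p,
      significant = !is.na(pMask) & pMask < alpha, alpha = alpha,
      nA = nA, nB = nB)
}

#' Write a Wilcoxon track as TSV
#'
#' @param track a [WilcoxonTrack-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeWilcoxonTrack <- function(track, path) {
  stopifnot(is(track, "WilcoxonTrack"))
  df <- data.frame(center = track@windowCenters, p = track@pValue,
                   significant = track@significant, nA = track@nA,
                   nB = track@nB)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", na = ".")
  invisible(path)
}

.getGroup <- function(groups, name) {
  if (!name %in% names(groups))
    stop(sprintf("unknown group '%s'; available: %s", name,
                 paste(names(groups), collapse = ", ")), call. = FALSE)
  groups[[name]]
}

#' Set algebra over gene groups
#'
#' Intersection, difference and union of two named groups from a
#' gene-group table, with sizes — the bookkeeping behind statements like
#' "three genes are shared between the endogenously expressed and the
#' RA-induced groups".
#'
#' @param groups named list of gene-id vectors (e.g. [hoxGeneGroups()]).
#' @param a,b group names present in `groups`.
#' @return list with sorted character vectors `intersection`,
#'   `aMinusB`, `bMinusA`, `union` and an integer vector `sizes`.
#' @examples
#' ops <- groupOps(hoxGeneGroups(), "9 hf WT expressed",
#'                 "6 hpf RA treated induced")
#' ops$intersection   # hoxb1a hoxb5b hoxb6b
#' @export
groupOps <- function(groups, a, b) {
  ga <- .getGroup(groups, a)
  gb <- .getGroup(groups, b)
  res <- list(intersection = sort(intersect(ga, gb)),
              aMinusB = sort(setdiff(ga, gb)),
              bMinusA = sort(setdiff(gb, ga)),
              union = sort(union(ga, gb)))
  res$sizes <- c(a = length(ga), b = length(gb),
                 intersection = length(res$intersection),
                 aMinusB = length(res$aMinusB),
                 bMinusA = length(res$bMinusA),
                 union = length(res$union))
  res
}
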