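# Shared fixtures: small on-disk tables, a standard pipeline wrapper over
# a simulated experiment, and a brute-force rank-sum oracle.

writeTempProbes <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tchrom\tstart\tend", rows), f)
  f
}

writeTempBed <- function(rows) {
  f <- tempfile(fileext = ".bed")
  writeLines(rows, f)
  f
}

# Evenly tiled probes (50 bp every 20 bp) across [0, len) on one chromosome.
tiledProbes <- function(len, chrom = "sim1", probeLength = 50, step = 20) {
  starts <- seq(0, len - probeLength, by = step)
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = starts + 1, width = probeLength))
  S4Vectors::mcols(gr)$probe_id <- sprintf("p%05d", seq_along(gr))
  S4Vectors::mcols(gr)$center <- starts + probeLength / 2
  gr
}

makeTssGRanges <- function(gene_id, tss, strand, chrom = "sim1") {
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = tss + 1, width = 1), strand = strand)
  S4Vectors::mcols(gr)$gene_id <- gene_id
  S4Vectors::mcols(gr)$tss <- tss
  gr
}

# log2-ratio -> replicate average -> TSS mapping for a simulated experiment.
simRelativeSignals <- function(sim, flank = 600) {
  ratios <- computeLog2Ratio(sim$signal)
  avg <- suppressWarnings(averageReplicates(ratios))
  mapProbesToTss(sim$probes, stats::setNames(avg$log2_ratio, avg$probe_id),
                 sim$tss, flank = flank)
}

# Full default pipeline from a simulated experiment to a PeakSet.
simPeaks <- function(sim, ...) {
  rel <- simRelativeSignals(sim)
  genes <- S4Vectors::mcols(sim$tss)$gene_id
  callPeaks(smoothLowess(aggregateWindows(rel, genes)), ...)
}

# Brute-force two-sided rank-sum p-value: enumerate every assignment of
# the pooled ranks to group A, build the exact distribution of the
# Mann-Whitney U statistic, and double the smaller tail (capped at 1).
bruteRanksumP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  ranks <- seq_len(n1 + n2)
  uAll <- apply(sets, 2, function(ix) sum(ranks[ix]) - n1 * (n1 + 1) / 2)
  pLo <- mean(uAll <= uObs)
  pHi <- mean(uAll >= uObs)
  min(1, 2 * min(pLo, pHi))
}
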