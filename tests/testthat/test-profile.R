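test_that("log2 ratios follow the two-channel definition", {
  tab <- data.frame(probe_id = c("p1", "p2", "p3"),
                    mnase = c(500, 800, 300), gdna = c(500, 400, 1200),
                    replicate_id = "r1", sample_id = "s1")
  expect_equal(computeLog2Ratio(tab)$log2_ratio, c(0, 1, -2))

  tab$gdna[1] <- -1
  expect_error(computeLog2Ratio(tab), "p1")
})

test_that("median centering zeroes each array's median ratio", {
  tab <- data.frame(probe_id = paste0("p", 1:5), mnase = c(2, 4, 8, 16, 32),
                    gdna = 1, replicate_id = "r1", sample_id = "s1")
  centered <- computeLog2Ratio(tab, medianCenter = TRUE)
  expect_equal(stats::median(centered$log2_ratio), 0)
  expect_equal(centered$log2_ratio, c(1:5) - 3)
})

test_that("replicate averaging takes means and flags partial coverage", {
  ratios <- data.frame(
    probe_id = c("p1", "p1", "p2", "p3", "p3", "p3"),
    sample_id = "s1",
    replicate_id = c("r1", "r2", "r1", "r1", "r2", "r3"),
    log2_ratio = c(0.4, 0.6, 0.7, -1, 0, 1))
  expect_warning(averageReplicates(ratios), "fewer than")
  avg <- suppressWarnings(averageReplicates(ratios))
  avg <- avg[order(avg$probe_id), ]
  expect_equal(avg$log2_ratio, c(0.5, 0.7, 0))
  expect_equal(avg$n_replicates, c(2L, 1L, 3L))
})

test_that("replicate concordance is affine-invariant and bounded", {
  x <- setNames(c(0.1, 0.5, -0.3, 0.8, 0.2), paste0("p", 1:5))
  expect_equal(replicateConcordance(x, x), 1.0)
  expect_equal(replicateConcordance(x, 2 * x + 3), 1.0)

  set.seed(42)
  a <- setNames(rnorm(1000), paste0("q", 1:1000))
  b <- setNames(rnorm(1000), paste0("q", 1:1000))
  expect_lt(replicateConcordance(a, b), 0.05)

  flat <- setNames(rep(1, 5), names(x))
  expect_warning(r2 <- replicateConcordance(x, flat), "zero variance")
  expect_true(is.na(r2))
})

test_that("probe-to-TSS mapping is strand-aware and flank-bounded", {
  probes <- tiledProbes(12000)
  ids <- S4Vectors::mcols(probes)$probe_id
  signal <- setNames(rep(0.3, length(ids)), ids)
  tss <- makeTssGRanges(c("plus", "minus"), c(5005, 5005), c("+", "-"))
  rel <- mapProbesToTss(probes, signal, tss)

  plus <- rel[rel$gene_id == "plus", ]
  minus <- rel[rel$gene_id == "minus", ]
  # a probe centered at 5105 maps to +100 on the plus gene, -100 on minus
  p <- ids[S4Vectors::mcols(probes)$center == 5105]
  expect_equal(plus$rel_pos[plus$probe_id == p], 100)
  expect_equal(minus$rel_pos[minus$probe_id == p], -100)
  # flank boundary: |rel| <= 600 kept, beyond dropped
  expect_true(all(abs(rel$rel_pos) <= 600))
  expect_true(any(plus$rel_pos == 600))
  p700 <- ids[S4Vectors::mcols(probes)$center == 5705]
  expect_false(p700 %in% plus$probe_id)

  far <- makeTssGRanges("offchrom", 5000, "+", chrom = "chr9")
  expect_warning(none <- mapProbesToTss(probes, signal, far), "no probe")
  expect_equal(nrow(none), 0)
})

test_that("window aggregation pools half-open 30/10 windows", {
  const <- data.frame(gene_id = "g", probe_id = "p", rel_pos = seq(-600, 600, 20),
                      log2_ratio = 0.3)
  tr <- aggregateWindows(const, "g")
  expect_true(all(abs(meanSignal(tr)[nPoints(tr) > 0] - 0.3) < 1e-12))

  two <- data.frame(gene_id = "g", probe_id = c("a", "b"),
                    rel_pos = c(-14, 14), log2_ratio = c(1, 0))
  tr2 <- aggregateWindows(two, "g")
  at <- function(x) which(windowCenters(tr2) == x)
  expect_equal(meanSignal(tr2)[at(0)], 0.5)      # both inside [-15, 15)
  expect_equal(nPoints(tr2)[at(0)], 2L)
  expect_equal(meanSignal(tr2)[at(-10)], 1)      # only -14 in [-25, 5)
  expect_equal(meanSignal(tr2)[at(20)], 0)       # only +14 in [5, 35)
  expect_true(is.na(meanSignal(tr2)[at(100)]))   # empty window
  expect_equal(nPoints(tr2)[at(100)], 0L)

  expect_error(aggregateWindows(two, character()), "empty gene set")
})

test_that("lowess smoothing preserves lines and reduces noise", {
  lin <- data.frame(gene_id = "g", probe_id = "p",
                    rel_pos = seq(-600, 600, 20), log2_ratio = NA)
  lin$log2_ratio <- 2 * lin$rel_pos + 1
  trLin <- aggregateWindows(lin, "g")
  smLin <- smoothLowess(trLin, spanF = 0.3)
  keep <- !is.na(meanSignal(trLin))
  expect_equal(trackValues(smLin), meanSignal(trLin)[keep], tolerance = 1e-6)

  constTr <- aggregateWindows(transform(lin, log2_ratio = 0.7), "g")
  expect_equal(unique(round(trackValues(smoothLowess(constTr)), 10)), 0.7)

  set.seed(7)
  x <- seq(-600, 600, 10)
  truth <- sin(x / 120)
  noisy <- truth + rnorm(length(x), sd = 0.1)
  tr <- new("WindowTrack", windowCenters = x, meanSignal = noisy,
            nPoints = rep(1L, length(x)), windowWidth = 30, step = 10)
  sm <- smoothLowess(tr, spanF = 0.1)
  rmse <- function(v) sqrt(mean((v - truth)^2))
  expect_lt(rmse(trackValues(sm)), rmse(noisy))

  tiny <- new("WindowTrack", windowCenters = c(0, 10), meanSignal = c(1, 2),
              nPoints = c(1L, 1L), windowWidth = 30, step = 10)
  expect_error(smoothLowess(tiny), "larger span")
})

test_that("scaling the MNase channel shifts profiles by exactly log2 k", {
  sim <- simulateExperiment(makeStageConfig("partial", nCells = 150, seed = 3))
  genes <- S4Vectors::mcols(sim$tss)$gene_id

  track <- function(signal) {
    ratios <- computeLog2Ratio(signal)
    avg <- suppressWarnings(averageReplicates(ratios))
    rel <- mapProbesToTss(sim$probes,
                          setNames(avg$log2_ratio, avg$probe_id), sim$tss)
    aggregateWindows(rel, genes)
  }
  base <- track(sim$signal)
  scaled <- sim$signal
  scaled$mnase <- scaled$mnase * 8
  shifted <- track(scaled)
  expect_equal(meanSignal(shifted), meanSignal(base) + 3, tolerance = 1e-12)
  expect_equal(nPoints(shifted), nPoints(base))
})

test_that("strand flip plus coordinate reflection mirrors the track", {
  probes <- tiledProbes(10000)
  ids <- S4Vectors::mcols(probes)$probe_id
  centers <- S4Vectors::mcols(probes)$center
  set.seed(11)
  signal <- setNames(rnorm(length(ids)), ids)
  tssAt <- 5000

  fwd <- mapProbesToTss(probes, signal,
                        makeTssGRanges("g", tssAt, "+"))
  # reflect every probe interval about the TSS and flip the gene's strand
  starts0 <- GenomicRanges::start(probes) - 1
  ends0 <- GenomicRanges::end(probes)
  refl <- GenomicRanges::GRanges("sim1",
    IRanges::IRanges(start = (2 * tssAt - ends0) + 1, end = 2 * tssAt - starts0))
  S4Vectors::mcols(refl)$probe_id <- ids
  S4Vectors::mcols(refl)$center <- 2 * tssAt - centers
  rev <- mapProbesToTss(refl, signal, makeTssGRanges("g", tssAt, "-"))

  trF <- aggregateWindows(fwd, "g")
  trR <- aggregateWindows(rev, "g")
  expect_equal(meanSignal(trF), meanSignal(trR), tolerance = 1e-12)
  expect_equal(nPoints(trF), nPoints(trR))
})

test_that("aggregation over a union is the n-weighted mean of the parts", {
  sim <- simulateExperiment(makeStageConfig("partial", nCells = 100, seed = 5))
  rel <- simRelativeSignals(sim)
  genes <- S4Vectors::mcols(sim$tss)$gene_id
  setA <- genes[1:10]; setB <- genes[11:37]
  tA <- aggregateWindows(rel, setA)
  tB <- aggregateWindows(rel, setB)
  tU <- aggregateWindows(rel, genes)
  nA <- nPoints(tA); nB <- nPoints(tB)
  pooled <- (ifelse(nA > 0, meanSignal(tA), 0) * nA +
             ifelse(nB > 0, meanSignal(tB), 0) * nB) / (nA + nB)
  expect_equal(nPoints(tU), nA + nB)
  expect_equal(meanSignal(tU)[nA + nB > 0], pooled[nA + nB > 0],
               tolerance = 1e-12)
})

test_that("the window track is deterministic for identical inputs", {
  sim1 <- simulateExperiment(makeStageConfig("ordered", nCells = 100, seed = 9))
  sim2 <- simulateExperiment(makeStageConfig("ordered", nCells = 100, seed = 9))
  expect_identical(sim1$signal, sim2$signal)
  t1 <- aggregateWindows(simRelativeSignals(sim1),
                         S4Vectors::mcols(sim1$tss)$gene_id)
  t2 <- aggregateWindows(simRelativeSignals(sim2),
                         S4Vectors::mcols(sim2$tss)$gene_id)
  expect_identical(meanSignal(t1), meanSignal(t2))
})
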