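## Generative model of an MNase-chip experiment.  Each cell of a
## population carries each configured nucleosome with probability
## `occupancy`, jittered around its template center by `fuzziness`;
## protected fragments (~147 bp) are "hybridized" to the probe tile by
## basepair overlap, a uniform free-DNA background is added, and two
## replicate channels are produced by re-noising the same protection
## landscape.  The gDNA control channel is uniform expected coverage.

.defaultGenes <- function(nGenes = 37, spacing = 4000, group = "all") {
  tss <- spacing / 2 + (seq_len(nGenes) - 1) * spacing
  data.frame(gene_id = sprintf("g%02d", seq_len(nGenes)),
             tss = tss,
             strand = rep(c("+", "-"), length.out = nGenes),
             group = group)
}

#' Construct a simulation configuration
#'
#' Defaults follow the assayed system: 50 bp probes every 20 bp, ~147 bp
#' of protected DNA per nucleosome, an aggregate over 37 promoters, and
#' a 2000-cell population.  Multiplicative log-normal channel noise
#' (sd 0.06 on the natural-log scale) is set deliberately low, at the
#' clean end of what well-replicated two-channel arrays achieve
#' (replicate concordance r^2 ~ 0.9), so that the qualitative character
#' of each simulated chromatin state is a property of the configuration
#' rather than of the noise draw.
#'
#' @param genes data.frame (`gene_id`, `tss` 0-based bp, `strand`,
#'   `group`); the default lays out 37 genes of alternating strand every
#'   4000 bp.
#' @param groupTemplates named list of template data.frames
#'   (`rel_center`, `occupancy`, `fuzziness`), one entry per gene group.
#' @param nCells cells in the population (default 2000).
#' @param genomeLength bp; default fits the gene layout.
#' @param wrapLength mean protected-fragment length (default 147 bp).
#' @param fragmentLengthSd sd of the fragment length (default 10 bp).
#' @param probeLength,probeStep array design (defaults 50, 20 bp).
#' @param backgroundRate free-DNA coverage per bp per cell (default 0.3,
#'   so depleted regions stay measurable rather than blank).
#' @param gdnaCoverage gDNA-channel coverage per bp per cell (default 1).
#' @param channelNoiseSd,gdnaNoiseSd log-normal noise sd (default 0.06).
#' @param seed integer RNG seed.
#' @return a [SimulationConfig-class].
#' @export
makeSimulationConfig <- function(genes = .defaultGenes(),
                                 groupTemplates,
                                 nCells = 2000,
                                 genomeLength = NULL,
                                 wrapLength = 147,
                                 fragmentLengthSd = 10,
                                 probeLength = 50,
                                 probeStep = 20,
                                 backgroundRate = 0.3,
                                 gdnaCoverage = 1,
                                 channelNoiseSd = 0.06,
                                 gdnaNoiseSd = 0.06,
                                 seed = 1L) {
  if (is.null(genomeLength))
    genomeLength <- max(genes$tss) + min(genes$tss)
  new("SimulationConfig", genomeLength = genomeLength, genes = genes,
      groupTemplates = groupTemplates, nCells = as.integer(nCells),
      wrapLength = wrapLength, fragmentLengthSd = fragmentLengthSd,
      probeLength = probeLength, probeStep = probeStep,
      backgroundRate = backgroundRate, gdnaCoverage = gdnaCoverage,
      channelNoiseSd = channelNoiseSd, gdnaNoiseSd = gdnaNoiseSd,
      seed = as.integer(seed))
}

#' Stage-like simulation configurations
#'
#' Three canonical promoter chromatin states observed across early
#' development, as simulator configs:
#'
#' * `"disordered"`: nucleosomes of high fuzziness (200 bp) and low
#'   occupancy (0.3) blanketing the whole region and well beyond the
#'   scored flank — the aggregate profile is essentially featureless.
#' * `"partial"`: three downstream nucleosomes at +60, +260 and +480 bp
#'   (spacings 200 and 220 bp) at moderate occupancy, upstream still
#'   disordered-free; the first peaks to emerge.
#' * `"ordered"`: five well-positioned nucleosomes, -1 at -170 and +1 at
#'   +115 bp (285 bp separation, i.e. an NDR slightly shorter than one
#'   nucleosome), +1 at elevated occupancy, and the remaining peaks one
#'   170 bp repeat further out (-340, -510, +285).  The outer offsets sit
#'   at the gel-derived repeat because protected fragments of ~147 bp
#'   cannot produce distinct aggregate maxima closer than ~one footprint;
#'   printed aggregate spacings below that arise from mixing gene groups
#'   with different positions, not from a single-population repeat.
#'
#' @param stage `"disordered"`, `"partial"` or `"ordered"`.
#' @param nCells,seed passed to [makeSimulationConfig()].
#' @return a [SimulationConfig-class].
#' @export
makeStageConfig <- function(stage = c("disordered", "partial", "ordered"),
                            nCells = 2000, seed = 1L) {
  stage <- match.arg(stage)
  tpl <- switch(stage,
    disordered = data.frame(rel_center = seq(-1000, 1000, by = 100),
                            occupancy = 0.3, fuzziness = 200),
    partial = data.frame(rel_center = c(60, 260, 480),
                         occupancy = c(0.55, 0.5, 0.5),
                         fuzziness = 30),
    ordered = data.frame(rel_center = c(-510, -340, -170, 115, 285),
                         occupancy = c(0.55, 0.6, 0.65, 0.9, 0.7),
                         fuzziness = 20))
  makeSimulationConfig(groupTemplates = list(all = tpl), nCells = nCells,
                       seed = seed)
}

# Probe tile covering the simulated genome (0-based design table -> GRanges).
.simProbes <- function(config) {
  starts <- seq(0, config@genomeLength - config@probeLength,
                by = config@probeStep)
  gr <- GRanges("sim1", IRanges(start = starts + 1, width = config@probeLength))
  mcols(gr)$probe_id <- sprintf("probe_%05d", seq_along(gr))
  mcols(gr)$center <- starts + config@probeLength / 2
  gr
}

.simTss <- function(config) {
  g <- config@genes
  gr <- GRanges("sim1", IRanges(start = g$tss + 1, width = 1),
                strand = g$strand)
  mcols(gr)$gene_id <- g$gene_id
  mcols(gr)$tss <- g$tss
  gr
}

# Expected TSS-relative probe signal and the aggregate truth peaks,
# computed from the model expectation (no sampling): per-bp protection
# probability = occupancy * P(protected fragment covers the bp), edges
# softened by fuzziness and length variation, then averaged over the
# probe footprint, group-weighted, background added, and log2-ratioed
# against the uniform gDNA expectation.
.expectedTruth <- function(config, flank = 600) {
  grid <- seq(-flank - config@probeLength, flank + config@probeLength)
  groups <- config@groupTemplates
  w <- table(factor(config@genes$group, levels = names(groups)))
  w <- as.numeric(w) / sum(w)
  cov <- numeric(length(grid))
  for (gi in seq_along(groups)) {
    tpl <- groups[[gi]]
    gcov <- numeric(length(grid))
    for (k in seq_len(nrow(tpl))) {
      s <- sqrt(tpl$fuzziness[k]^2 + config@fragmentLengthSd^2 / 4)
      half <- config@wrapLength / 2
      d <- grid - tpl$rel_center[k]
      gcov <- gcov + tpl$occupancy[k] *
        (pnorm((d + half) / max(s, 1e-6)) - pnorm((d - half) / max(s, 1e-6)))
    }
    cov <- cov + w[gi] * gcov
  }
  cov <- cov + config@backgroundRate
  # average over the probe footprint centered at each position
  cs <- cumsum(cov)
  halfp <- config@probeLength / 2
  i <- seq_along(grid)
  lo <- pmax(1, i - floor(halfp)); hi <- pmin(length(grid), i + floor(halfp))
  probeMean <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
  ratio <- log2(probeMean / config@gdnaCoverage)
  keep <- abs(grid) <= flank
  profile <- data.frame(rel_pos = grid[keep], expected_log2_ratio = ratio[keep])
  tr <- new("SmoothTrack", positions = profile$rel_pos,
            value = profile$expected_log2_ratio, spanF = 1)
  pk <- callPeaks(tr)
  list(expectedProfile = profile, peaks = peaksTable(pk))
}

#' Simulate a full MNase-chip experiment
#'
#' Draws a cell population according to the configuration, converts the
#' protected fragments to per-probe basepair-overlap intensities, adds
#' the uniform free-DNA background, and emits two replicate two-channel
#' signal tables (the same protection landscape re-noised per replicate)
#' together with the probe design, the TSS annotation, and the ground
#' truth (realized templates, the expected TSS-relative profile, and the
#' expected aggregate peak list).  Deterministic given the seed.
#'
#' @param config a [SimulationConfig-class].
#' @param sampleId sample label written into the signal table.
#' @param keepFragments logical; also return the realized fragments (as
#'   an [IRanges::IRanges] plus gene ids) for bookkeeping checks.
#' @return list with elements `probes` (GRanges), `signal` (long-format
#'   two-channel data.frame, replicates `rep1`/`rep2`), `tss` (GRanges),
#'   `truth` (list), and optionally `fragments`.
#' @examples
#' \donttest{
#' sim <- simulateExperiment(makeStageConfig("ordered", nCells = 200))
#' head(sim$signal)
#' }
#' @export
simulateExperiment <- function(config, sampleId = "sim",
                               keepFragments = FALSE) {
  validObject(config)
  genes <- config@genes
  half <- config@wrapLength / 2
  for (i in seq_len(nrow(genes))) {
    tpl <- config@groupTemplates[[genes$group[i]]]
    sgn <- if (genes$strand[i] == "+") 1 else -1
    ctr <- genes$tss[i] + sgn * tpl$rel_center
    if (any(ctr - half < 0 | ctr + half > config@genomeLength))
      stop(sprintf("template beyond genome bounds for gene '%s'",
                   genes$gene_id[i]), call. = FALSE)
  }

  set.seed(config@seed)
  fragStart <- integer(0); fragEnd <- integer(0); fragGene <- character(0)
  for (i in seq_len(nrow(genes))) {
    tpl <- config@groupTemplates[[genes$group[i]]]
    sgn <- if (genes$strand[i] == "+") 1 else -1
    for (k in seq_len(nrow(tpl))) {
      nPresent <- rbinom(1, config@nCells, tpl$occupancy[k])
      if (!nPresent) next
      rel <- tpl$rel_center[k] + rnorm(nPresent, 0, tpl$fuzziness[k])
      len <- pmax(1, round(rnorm(nPresent, config@wrapLength,
                                 config@fragmentLengthSd)))
      ctr <- genes$tss[i] + sgn * rel
      s <- pmax(0L, as.integer(round(ctr - len / 2)))
      e <- pmax(pmin(as.integer(config@genomeLength), s + len), s + 1L)
      fragStart <- c(fragStart, s); fragEnd <- c(fragEnd, e)
      fragGene <- c(fragGene, rep(genes$gene_id[i], nPresent))
    }
  }
  frags <- IRanges(start = fragStart + 1L, end = fragEnd)  # 1-based closed

  probes <- .simProbes(config)
  cov <- coverage(frags, width = config@genomeLength)
  overlap <- as.numeric(viewSums(Views(cov, start = start(probes),
                                       end = end(probes))))
  bg <- config@backgroundRate * config@nCells * config@probeLength
  mnaseExp <- overlap + bg
  gdnaExp <- config@gdnaCoverage * config@nCells * config@probeLength

  nP <- length(probes)
  reps <- lapply(1:2, function(r) {
    set.seed(config@seed + r)
    data.frame(probe_id = mcols(probes)$probe_id,
               mnase = mnaseExp * exp(rnorm(nP, 0, config@channelNoiseSd)),
               gdna = gdnaExp * exp(rnorm(nP, 0, config@gdnaNoiseSd)),
               replicate_id = paste0("rep", r),
               sample_id = sampleId)
  })
  signal <- do.call(rbind, reps)

  truth <- .expectedTruth(config)
  truth$templates <- lapply(
    setNames(genes$gene_id, genes$gene_id),
    function(g) config@groupTemplates[[genes$group[genes$gene_id == g]]])

  out <- list(probes = probes, signal = signal, tss = .simTss(config),
              truth = truth)
  if (keepFragments)
    out$fragments <- list(ranges = frags, gene_id = fragGene)
  out
}

#' Write a simulated experiment to a directory
#'
#' Emits the same TSV/BED dialects the readers consume (`probes.tsv`,
#' `signal.tsv`, `tss.bed`) plus the ground truth as `truth.json`.
#'
#' @param sim result of [simulateExperiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeProbes(sim$probes, file.path(dir, "probes.tsv"))
  writeSignalTable(sim$signal, file.path(dir, "signal.tsv"))
  writeTss(sim$tss, file.path(dir, "tss.bed"))
  jsonlite::write_json(
    list(peaks = sim$truth$peaks,
         expectedProfile = sim$truth$expectedProfile,
         templates = sim$truth$templates),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
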