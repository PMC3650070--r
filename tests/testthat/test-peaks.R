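makeTrack <- function(x, y) new("SmoothTrack", positions = x, value = y,
                                spanF = 0.05)

gaussBumps <- function(x, centers, amp, sd = 40) {
  y <- numeric(length(x))
  for (i in seq_along(centers)) y <- y + amp[i] * exp(-(x - centers[i])^2 / (2 * sd^2))
  y
}

test_that("fragment-size arithmetic derives linker and spacing ranges", {
  m <- fragmentSizeModel()
  expect_equal(linkerRange(m), c(20, 60))
  expect_equal(spacingRange(m), c(170, 210))

  zero <- fragmentSizeModel(diRange = c(300, 300), monoRef = 150)
  expect_equal(linkerRange(zero), c(0, 0))
  expect_equal(spacingRange(zero), c(150, 150))

  alt <- fragmentSizeModel(monoRange = c(140, 160), diRange = c(310, 330),
                           monoRef = 140)
  expect_equal(linkerRange(alt), c(30, 50))
  expect_equal(spacingRange(alt), c(170, 190))
  # round-trip: spacing - monoRef recovers the linker
  expect_equal(spacingRange(alt) - 140, linkerRange(alt))

  expect_error(fragmentSizeModel(diRange = c(250, 360), monoRef = 150),
               "negative linker")
})

test_that("peak calling finds bumps, honors separation, skips monotone tracks", {
  x <- seq(-600, 600, 10)

  mono <- makeTrack(x, x / 100)
  expect_equal(nrow(peaksTable(callPeaks(mono))), 0)

  two <- makeTrack(x, gaussBumps(x, c(-170, 115), c(0.5, 0.5)))
  pk <- peaksTable(callPeaks(two))
  expect_equal(nrow(pk), 2)
  expect_true(all(abs(pk$center - c(-170, 115)) <= 10))
  expect_equal(pk$label, c(-1L, 1L))

  # two bumps 50 bp apart: only the higher survives a 100 bp separation
  close <- makeTrack(x, gaussBumps(x, c(0, 50), c(0.4, 0.6), sd = 15))
  pkc <- peaksTable(callPeaks(close, minSeparation = 100))
  expect_equal(nrow(pkc), 1)
  expect_lt(abs(pkc$center - 50), 11)

  # plateau takes its centroid
  plat <- makeTrack(x, ifelse(x >= -20 & x <= 20, 1, 0))
  expect_equal(peaksTable(callPeaks(plat))$center, 0)
})

test_that("peak calling is translation-equivariant and amplitude-scalable", {
  x <- seq(-600, 600, 10)
  y <- gaussBumps(x, c(-300, -50, 200), c(0.3, 0.6, 0.4))
  base <- peaksTable(callPeaks(makeTrack(x, y)))

  shifted <- peaksTable(callPeaks(makeTrack(x + 70, y)))
  expect_equal(shifted$center, base$center + 70)

  k <- 3.5
  scaled <- peaksTable(callPeaks(makeTrack(x, k * y),
                                 minProminence = 0.05 * k))
  expect_equal(scaled$center, base$center)
  expect_equal(scaled$prominence, k * base$prominence, tolerance = 1e-12)
})

test_that("peaks are labeled outward from the TSS", {
  expect_equal(labelPeaks(c(-450, -290, -170, 115, 250)),
               c(-3L, -2L, -1L, 1L, 2L))
  expect_equal(labelPeaks(c(60, 260, 480)), c(1L, 2L, 3L))
  expect_equal(labelPeaks(0), 1L)
})

test_that("spacings are successive center differences", {
  x <- seq(-600, 600, 10)
  pk <- callPeaks(makeTrack(x, gaussBumps(x, c(60, 260, 480), rep(0.5, 3))))
  expect_equal(peakSpacings(pk), c(200, 220))

  up <- callPeaks(makeTrack(x, gaussBumps(x, c(-450, -290), c(0.5, 0.5))))
  expect_equal(peakSpacings(up), 160)

  one <- callPeaks(makeTrack(x, gaussBumps(x, 0, 0.5)))
  expect_length(peakSpacings(one), 0)
})

test_that("NDR width is the -1/+1 separation minus one footprint", {
  x <- seq(-605, 595, 10)   # grid aligned with the bump centers
  pk <- callPeaks(makeTrack(x, gaussBumps(x, c(-175, 115), c(0.5, 0.6))))
  ndr <- ndrWidth(pk)                     # separation 290, footprint 160
  expect_true(ndr@called)
  expect_equal(ndr@separation, 290)
  expect_equal(ndr@width, 130)

  flat <- fragmentSizeModel(footprint = 290)
  expect_equal(ndrWidth(pk, flat)@width, 0)

  wide <- callPeaks(makeTrack(x, gaussBumps(x, c(-235, 235), c(0.5, 0.6))))
  expect_equal(ndrWidth(wide)@width, 470 - 160)

  down <- callPeaks(makeTrack(x, gaussBumps(x, c(115, 305), c(0.6, 0.5))))
  no <- ndrWidth(down)
  expect_false(no@called)
  expect_match(no@reason, "-1")
})

test_that("occupancy ratios compare -1 and +1 densities", {
  x <- seq(-605, 595, 10)
  sym <- callPeaks(makeTrack(x, gaussBumps(x, c(-175, 115), c(0.5, 0.5))))
  expect_equal(occupancyRatio(sym), 1.0, tolerance = 1e-9)

  expect_equal(percentReduction(0.65, 1.0), 35)
  expect_error(percentReduction(0.5, 0), "positive")

  single <- callPeaks(makeTrack(x, gaussBumps(x, 115, 0.6)))
  expect_warning(r <- occupancyRatio(single), "both -1 and \\+1")
  expect_true(is.na(r))
})

test_that("a halved -1 occupancy shows as a ~50% drop in the density ratio", {
  mkcfg <- function(occm1, seed) makeSimulationConfig(
    groupTemplates = list(all = data.frame(
      rel_center = c(-425, -255, -85, 85, 255),
      occupancy = c(0.55, 0.6, occm1, 0.9, 0.7), fuzziness = 20)),
    backgroundRate = 0.1, seed = seed)
  ref <- occupancyRatio(simPeaks(simulateExperiment(mkcfg(0.8, seed = 21))))
  low <- occupancyRatio(simPeaks(simulateExperiment(mkcfg(0.4, seed = 22))))
  expect_lt(abs(percentReduction(low, ref) - 50), 10)
})

test_that("noiseless well-spaced nucleosomes are recovered within one step", {
  centers <- c(-400, -180, 30, 250, 470)
  cfg <- makeSimulationConfig(
    groupTemplates = list(all = data.frame(
      rel_center = centers,
      occupancy = c(0.3, 0.5, 0.7, 0.9, 0.4),
      fuzziness = c(0, 10, 20, 30, 40))),
    channelNoiseSd = 0, gdnaNoiseSd = 0, seed = 33)
  pk <- peaksTable(simPeaks(simulateExperiment(cfg)))
  expect_equal(nrow(pk), 5)
  for (ctr in centers)
    expect_lte(min(abs(pk$center - ctr)), 10)
})
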