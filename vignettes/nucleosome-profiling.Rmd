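---
title: "Methods: aggregate nucleosome profiling from MNase tiling arrays"
author: "nucleoprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aggregate nucleosome profiling from MNase tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the model

A nucleosome wraps ~147 bp of DNA around a histone octamer.  Micrococcal
nuclease (MNase) digests the unprotected linker DNA between nucleosomes,
so the surviving mononucleosome-sized fragments mark where nucleosomes
sat in each cell.  In the MNase-chip design this package models, those
fragments are hybridized to a tiling array of 50 bp probes spaced every
20 bp, with randomly sheared genomic DNA (gDNA) in the second channel as
an abundance control.  The per-probe statistic is the log2 ratio of the
two channels:

$$ r_p = \log_2\!\frac{\mathrm{MNase}_p}{\mathrm{gDNA}_p} , $$

averaged across replicate digestions.  High $r_p$ means the probe's
genomic interval was frequently protected — a well-occupied nucleosome
position in the population; low $r_p$ means depletion.

Two population-level properties are distinguished throughout:
**positioning** (how reproducibly a nucleosome sits at the same place
across cells; its spread is "fuzziness") and **occupancy** (in what
fraction of cells the position is bound).  In an aggregate profile,
positioning controls peak width and occupancy controls peak amplitude.

## From probes to aggregate profiles

`mapProbesToTss()` places each probe at its strand-adjusted TSS-relative
offset, $d = s_g\,(x_p - t_g)$, keeping $|d| \le 600$ bp (inclusive at
the boundary).  Negative $d$ is always upstream of transcription, so
minus-strand genes contribute mirrored coordinates and a probe may serve
several genes.  Coordinates are BED-convention 0-based half-open on
disk; probe centers $(start+end)/2$ may be half-integral and are kept
real.

`aggregateWindows()` tallies all (gene, probe) records of a gene set in
a 30 bp window stepped every 10 bp across −600..+600.  Window
membership is half-open, $[c-15, c+15)$, which makes the overlapping
30/10 tiling unambiguous — every record falls in exactly three
consecutive windows.  By default records are pooled with equal weight,
which keeps the per-window observation count `nPoints` interpretable;
`perGeneMean = TRUE` switches the observation unit to per-gene window
means (each gene counted once).  Windows with no probe (e.g. inside
repeat-masked gaps the array design skipped) stay `NA` and are excluded
from all downstream steps rather than imputed: inventing signal inside
probe gaps would manufacture spurious peaks.

`smoothLowess()` fits a locally weighted linear regression through the
non-missing window means (span `f = 0.05` of the points, tricube
weights, 3 robustifying iterations — `stats::lowess`) and evaluates it
at the observed centers only.  With the default 121-window grid the
span covers ~6 windows (~60 bp), light enough to preserve nucleosome
peaks (~150-200 bp apart) while suppressing probe-level jitter.  The
smoother is fitted on the window track, not on pooled probe records;
for evenly covered windows the two are nearly identical and the window
track keeps the fit independent of probe density fluctuations.

## Peaks, labels, and promoter geometry

`callPeaks()` takes local maxima of the smoothed track (plateaus
contribute their centroid; track ends are never peaks), computes each
candidate's topographic prominence (height above the higher of the two
minima separating it from higher terrain), discards candidates below
`minProminence = 0.05` log2 units, and greedily retains survivors in
decreasing prominence order subject to `minSeparation = 100` bp.  The
separation default sits safely below the expected 170-210 bp
nucleosome repeat, so genuine neighbors are never merged, while
shoulder artifacts of a single broad peak are.  Peaks are labeled
outward from the TSS: +1, +2, … at $c \ge 0$, −1, −2, … at $c < 0$.  A
peak at exactly 0 is +1, a convention chosen so that every peak has a
label even when a nucleosome sits directly on the TSS.

`fragmentSizeModel()` encodes the gel-band arithmetic: with a
mono-nucleosome band of 150–175 bp and a di-nucleosome band of
320–360 bp, the linker range is the di band minus two reference mono
lengths and the expected peak-to-peak spacing is the reference mono
length plus the linker.  The reference is the band's lower edge
(150 bp): that single choice reproduces both derived ranges (linker
20–60 bp, spacing 170–210 bp) simultaneously, which the band midpoint
or upper edge does not.

`ndrWidth()` sizes the nucleosome-depleted region as the −1/+1
center-to-center separation minus one nucleosome footprint.  The
footprint default is 160 bp — inside the observed mono band, and the
value under which a 290 bp separation yields the ~130 bp NDR that the
same profile geometry implies.  Both are configurable.

`occupancyRatio()` reports the −1/+1 density ratio.  Peak amplitudes
are log2 values, so the ratio is computed on the linear scale,
$2^{a_{-1} - a_{+1}}$: on that scale halving the −1 occupancy halves
the ratio, which is the property that makes percent reductions between
conditions interpretable.  A literal quotient of the two log2
amplitudes is available (`scale = "log2"`) but is meaningful only when
both amplitudes are positive; aggregate log2 profiles routinely
straddle zero, so it is not the default.

## Comparing gene groups

`wilcoxonTrack()` compares two gene groups window by window with a
two-sided unpaired Wilcoxon rank-sum test.  The observation unit is the
per-gene window mean (`perGeneWindowMatrix()`): each gene contributes
one value per window, so a 6-gene group against a 31-gene group gives
n = 6 vs 31 at every window — the unit consistent with testing a
difference *between gene sets* rather than between probe pools.  The
exact null distribution is enumerated when both groups have ≤ 8
non-missing, tie-free values; otherwise the normal approximation with
midranks, tie-corrected variance and continuity correction is used
(both via `stats::wilcox.test`; the exact branch is verified against
brute-force enumeration in the test suite).  Raw p-values are
thresholded at α = 0.05 with no multiple-testing correction — the
classic per-window significance mask; a Benjamini–Hochberg option
(`adjust = "BH"`) is provided for modern use.  Under the null the
per-window false-positive fraction is calibrated (0.05 ± 0.02 over
1000 simulated windows; slightly conservative because the rank-sum
distribution is discrete).

## The synthetic-data generator

`simulateExperiment()` draws a complete experiment from an explicit
generative model.  For each gene and each of `nCells` cells, every
nucleosome template (TSS-relative center, occupancy, fuzziness) is
present with probability `occupancy`; present nucleosomes protect a
fragment of length ~Normal(147, 10) bp centered at the template
position plus Normal(0, fuzziness) jitter, strand-mirrored onto genomic
coordinates.  The MNase-channel intensity of a probe is the total
basepair overlap of all fragments with the probe, plus a uniform
free-DNA background, times log-normal noise; the gDNA channel is a
uniform expected coverage times log-normal noise.  Basepair overlap
(rather than fragment-midpoint counting) models hybridization of whole
fragments and makes total signal exactly conserved, which the test
suite checks by independent interval bookkeeping.  Two replicates
re-noise the same protection landscape with different sub-seeds, so
replicate concordance reflects channel noise only — as in a real
two-replicate digestion of one biological pool.  Everything is
deterministic given the seed.

The default layout aggregates 37 promoters (alternating strand, 4 kb
apart) with 2000 cells, matching the scale of a staged whole-embryo
promoter study.  Channel noise is log-normal with sd 0.06 (natural-log
scale), deliberately at the clean end of what well-replicated
two-channel arrays achieve (simulated replicate r² ≈ 0.93): the
simulator's role here is ground-truth recovery testing, and the low
noise floor makes the character of each simulated chromatin state a
property of its configuration rather than of the noise draw.  Noisier,
lower-concordance arrays are easily emulated by raising
`channelNoiseSd`.

`makeStageConfig()` provides three canonical promoter states:

* **disordered** — low-occupancy (0.3), high-fuzziness (200 bp)
  nucleosomes every 100 bp across ±1000 bp.  The blanket extends well
  past the scored ±600 bp flank so that expected coverage is flat over
  the whole window (a blanket ending at the flank leaves a broad
  coverage dome centered on the TSS that a sensitive caller would
  report).  The aggregate profile is featureless: the default caller
  finds no peak within ±300 bp.
* **partial** — nucleosomes at +60, +260 and +480 bp (spacings 200 and
  220 bp, inside the gel-derived repeat range) at moderate occupancy;
  the first downstream peaks to emerge, upstream still unstructured.
* **ordered** — five well-positioned nucleosomes with the −1/+1 pair
  at −170/+115 bp (285 bp separation, i.e. an NDR slightly shorter
  than one nucleosome footprint), elevated +1 occupancy (0.9), and the
  remaining nucleosomes one 170 bp repeat further out (−340, −510,
  +285 bp).

The outer positions of the ordered stage are a deliberate design
choice.  Protection profiles built from ~147 bp fragments read out by
50 bp probes are sums of ~197 bp-wide unimodal bumps, and two such
bumps closer than about one footprint cannot produce two distinct
aggregate maxima — the superposition between them always exceeds both
flanks.  Published aggregate profiles do show adjacent peaks only
120-135 bp apart, but such spacings arise from mixing gene groups whose
nucleosomes occupy different positions, not from a physical
sub-nucleosomal repeat in any one population.  A single-population
simulation therefore cannot place recoverable peaks at those offsets;
the ordered stage keeps the biologically central −1/+1 geometry exact
and spaces the outer nucleosomes at the measured repeat.  The
generator's ground truth (expected aggregate peak positions and
amplitudes) is computed from the model expectation — Gaussian-softened
protection probabilities convolved with the probe footprint — not from
the sampled fragments, so recovery tests compare the pipeline against
an analytic target.

What the simulator does **not** emulate: sequence-dependent nucleosome
affinity and MNase sequence bias, di-nucleosome carryover through the
gel cut (only mononucleosome fragments are emitted), probe-specific
hybridization efficiency and dye bias, and inter-array normalization
artifacts.  Tests passing on synthetic data therefore demonstrate that
the pipeline's inference is correct under the stated generative model,
not that real-array preprocessing upstream of the log ratio is solved —
channel normalization is taken as given (an optional per-array
median-centering switch exists in `computeLog2Ratio()`).

## Numerical choices and degenerate inputs

* Intensities must be strictly positive before the log ratio; offending
  probes are reported by id.
* Probes covered by a single replicate keep their value with a warning;
  replicate concordance is undefined (`NA`) when a replicate has zero
  variance.
* `smoothLowess()` refuses tracks with fewer than
  max(3, ceil(f·n)) usable windows rather than extrapolating.
* Peak ties in the greedy retention are broken by amplitude, then by
  position, making the caller fully deterministic; plateaus (exactly
  equal neighboring values) contribute their centroid.
* Rank-sum windows with fewer than two observations in either group are
  skipped (`NA`, never "significant").
* The NDR call degrades to a reasoned no-call, not an error, when the
  −1 or +1 peak is absent.
* All file formats are plain TSV/BED6 (UTF-8, tab-delimited, `.` for
  missing); genomic coordinates are 0-based half-open on disk and
  1-based GRanges in memory, converted only at the file boundary.

## Problem sizes

The test suite and the acceptance script run simulations of 37
promoters × 2000 cells (≈ 260k fragments, ≈ 7400 probes per
replicate) for recovery checks, 1000 simulated windows for null
calibration, and exhaustive rank-assignment enumeration up to group
sizes 5 vs 5 for exactness checks.  These sizes give binomial sampling
errors well inside the asserted tolerances (e.g. peak centers within
±20 bp, occupancy ratios within a few percent) while keeping a full
run in tens of seconds.

## Known limitations

* Aggregate profiles are population and gene-set averages; single-gene
  peak calls on one array are not guaranteed and are out of scope.
* Peaks closer than ~one nucleosome footprint are fundamentally
  unresolvable in protection coverage (see above); apparent sub-repeat
  spacings in mixed gene sets should be interpreted as positional
  heterogeneity between subsets.
* The Wilcoxon track tests each window marginally; neighboring windows
  share probes and are therefore correlated, so runs of significant
  windows should be read as regions, not counted as independent
  discoveries.
* Liftover between genome assemblies is out of scope: probes and TSS
  annotations are assumed to be on one assembly.
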