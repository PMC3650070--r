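Package: nucleoprof
Title: Nucleosome Profiling from Two-Channel MNase Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping nucleosome organization at promoters from
    MNase-chip experiments, in which mononucleosomal DNA and sheared
    genomic DNA are co-hybridized to a tiling microarray of 50 bp probes
    spaced every 20 bp. Probe-level log2(MNase/gDNA) ratios are placed on
    strand-adjusted TSS-relative coordinates, aggregated over gene sets
    with a 30 bp sliding window (10 bp step), and lowess-smoothed
    (f = 0.05) into aggregate nucleosome-density profiles. Peaks are
    called and labeled (-n..+n around the TSS), inter-nucleosome spacings
    and nucleosome-depleted-region (NDR) widths are derived together with
    gel-based mono-/di-nucleosome fragment-size arithmetic, -1/+1
    occupancy ratios are tracked across conditions, and gene groups are
    compared window-by-window with two-sided Wilcoxon rank-sum tests.
    A generative simulator of MNase-protection tiling-array experiments
    (configurable nucleosome positions, occupancy, and fuzziness across a
    cell population) provides ground-truth data for end-to-end testing,
    and a zebrafish hox promoter gene-group table ships as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
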