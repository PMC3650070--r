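## File formats: tab-separated tables with headers for probes, signals and
## gene groups; BED6 for TSS annotations.  Genomic coordinates are 0-based
## half-open on disk (BED convention) and converted to the usual 1-based
## GRanges representation in memory.

.stopIo <- function(path, fmt, ...) {
  stop(sprintf("%s: %s", path, sprintf(fmt, ...)), call. = FALSE)
}

#' Read a probe definition table
#'
#' Reads the tiled-array probe design: one row per probe with its genomic
#' interval (0-based half-open, e.g. a 50 bp probe every 20 bp).  Probe
#' centers, `(start + end) / 2`, are attached as metadata and may be
#' half-integral.
#'
#' @param path tab-separated file with header columns `probe_id`, `chrom`,
#'   `start`, `end`.
#' @return A [GenomicRanges::GRanges] with metadata columns `probe_id` and
#'   `center`; input order is preserved.
#' @examples
#' f <- tempfile()
#' writeLines(c("probe_id\tchrom\tstart\tend", "p1\tchr3\t100\t150"), f)
#' pr <- readProbes(f)
#' mcols(pr)$center   # 125
#' @export
readProbes <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   na.strings = NULL, quote = "", comment.char = "")
  need <- c("probe_id", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    .stopIo(path, "probe table must have columns %s", paste(need, collapse = ", "))
  start0 <- suppressWarnings(as.numeric(df$start))
  end0 <- suppressWarnings(as.numeric(df$end))
  bad <- which(is.na(start0) | is.na(end0) | df$probe_id == "" | df$chrom == "")
  if (length(bad))
    .stopIo(path, "malformed probe row at line %d", bad[1] + 1L)  # +1 for header
  if (any(end0 <= start0))
    .stopIo(path, "probe with end <= start at line %d", which(end0 <= start0)[1] + 1L)
  gr <- GRanges(df$chrom, IRanges(start = start0 + 1, end = end0))
  mcols(gr)$probe_id <- df$probe_id
  mcols(gr)$center <- (start0 + end0) / 2
  gr
}

#' Write a probe definition table
#'
#' Inverse of [readProbes()]: writes `probe_id`, `chrom`, `start`, `end`
#' (0-based half-open) as UTF-8 TSV.
#'
#' @param probes `GRanges` as returned by [readProbes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProbes <- function(probes, path) {
  df <- data.frame(probe_id = mcols(probes)$probe_id,
                   chrom = as.character(seqnames(probes)),
                   start = start(probes) - 1L,
                   end = end(probes))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Probe centers in 0-based coordinates
#'
#' @param probes `GRanges` from [readProbes()] (or any GRanges; centers are
#'   recomputed from the ranges when no `center` column is present).
#' @return numeric vector of probe center positions (bp, 0-based axis).
#' @export
probeCenters <- function(probes) {
  if (!is.null(mcols(probes)$center)) return(mcols(probes)$center)
  (start(probes) - 1 + end(probes)) / 2
}

#' Read a TSS annotation (BED6)
#'
#' One transcription start site per gene.  Under BED half-open semantics
#' the TSS (first transcribed base, 0-based) is the `start` field for
#' plus-strand genes and `end - 1` for minus-strand genes.
#'
#' @param path BED6 file; column 4 is the gene id, column 6 the strand
#'   (`+` or `-` only).
#' @return A width-1 [GenomicRanges::GRanges] at the TSS base, strand set,
#'   with metadata columns `gene_id` and `tss` (the 0-based coordinate).
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t1000\t3000\tgeneA\t0\t+",
#'              "chr1\t5000\t8000\tgeneB\t0\t-"), f)
#' tssPositions(readTss(f))   # geneA 1000, geneB 7999
#' @export
readTss <- function(path) {
  force(path)
  bed <- tryCatch(rtracklayer::import(path, format = "BED"),
                  error = function(e) .stopIo(path, "BED parse error: %s",
                                              conditionMessage(e)))
  str <- as.character(strand(bed))
  if (any(!str %in% c("+", "-")))
    .stopIo(path, "strand must be '+' or '-' for every gene (got '%s')",
            str[!str %in% c("+", "-")][1])
  ids <- mcols(bed)$name
  if (is.null(ids) || any(is.na(ids) | ids == ""))
    .stopIo(path, "every BED record needs a gene id in column 4")
  if (anyDuplicated(ids))
    .stopIo(path, "duplicate gene_id '%s' (one TSS per gene required)",
            ids[duplicated(ids)][1])
  # import() gives 1-based closed ranges; 0-based TSS is start-1 (+) or end-1 (-)
  tss0 <- ifelse(str == "+", start(bed) - 1L, end(bed) - 1L)
  gr <- GRanges(seqnames(bed), IRanges(start = tss0 + 1L, width = 1L), strand = str)
  mcols(gr)$gene_id <- ids
  mcols(gr)$tss <- tss0
  gr
}

#' Write a TSS annotation as BED6
#'
#' Each gene is written as a 1 bp BED feature at its TSS; round-trips
#' through [readTss()].
#'
#' @param tss width-1 `GRanges` as returned by [readTss()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTss <- function(tss, path) {
  df <- data.frame(chrom = as.character(seqnames(tss)),
                   start = mcols(tss)$tss,
                   end = mcols(tss)$tss + 1L,
                   name = mcols(tss)$gene_id,
                   score = 0L,
                   strand = as.character(strand(tss)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' TSS positions in 0-based coordinates
#'
#' @param tss `GRanges` from [readTss()].
#' @return named numeric vector (names = gene ids) of 0-based TSS positions.
#' @export
tssPositions <- function(tss) {
  setNames(as.numeric(mcols(tss)$tss), mcols(tss)$gene_id)
}

#' Validate and read a two-channel signal table
#'
#' Long-format probe intensities: one row per (probe, replicate, sample)
#' with strictly positive MNase-channel and gDNA-channel intensities
#' (positivity is required before taking log ratios).
#'
#' @param path TSV with header columns `probe_id`, `mnase`, `gdna`,
#'   `replicate_id`, `sample_id`.
#' @return data.frame with those columns.
#' @export
readSignalTable <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  validateSignalTable(df, context = path)
}

#' @rdname readSignalTable
#' @param table a data.frame to validate in place of a file.
#' @param context label used in error messages.
#' @export
validateSignalTable <- function(table, context = "signal table") {
  need <- c("probe_id", "mnase", "gdna", "replicate_id", "sample_id")
  if (!all(need %in% names(table)))
    stop(sprintf("%s: needs columns %s", context, paste(need, collapse = ", ")),
         call. = FALSE)
  bad <- which(!is.finite(table$mnase) | !is.finite(table$gdna) |
                 table$mnase <= 0 | table$gdna <= 0)
  if (length(bad))
    stop(sprintf("%s: non-positive intensity for probe '%s'",
                 context, table$probe_id[bad[1]]), call. = FALSE)
  key <- paste(table$probe_id, table$replicate_id, table$sample_id, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicate (probe, replicate, sample) row for probe '%s'",
                 context, table$probe_id[duplicated(key)][1]), call. = FALSE)
  table
}

#' @rdname readSignalTable
#' @export
writeSignalTable <- function(table, path) {
  validateSignalTable(table)
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write gene-group tables
#'
#' Gene groups are stored long-format: one row per (group, gene).
#'
#' @param path TSV with header columns `group_name`, `gene_id`.
#' @return named list mapping group name to a character vector of gene ids.
#' @export
readGeneGroups <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("group_name", "gene_id") %in% names(df)))
    .stopIo(path, "gene-group table needs columns group_name, gene_id")
  split(df$gene_id, factor(df$group_name, levels = unique(df$group_name)))
}

#' @rdname readGeneGroups
#' @param groups named list of character vectors.
#' @export
writeGeneGroups <- function(groups, path) {
  df <- data.frame(group_name = rep(names(groups), lengths(groups)),
                   gene_id = unlist(groups, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Zebrafish hox promoter gene groups
#'
#' The packaged expression grouping of the 37 single-TSS zebrafish *hox*
#' genes used throughout the examples: wild-type expressed (6) and
#' non-expressed (31) genes at 9 hpf, retinoic-acid-treated induced (9)
#' and uninduced (28) genes at 6 hpf, and the 6 genes induced only by RA
#' ("RA-only").  Genes may appear in several groups.
#'
#' @return named list of 5 character vectors of gene ids.
#' @examples
#' lengths(hoxGeneGroups())
#' @export
hoxGeneGroups <- function() {
  readGeneGroups(system.file("extdata", "hox_expression_groups.tsv",
                             package = "nucleoprof", mustWork = TRUE))
}
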