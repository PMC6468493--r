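#' @importFrom data.table data.table setkey setorder rbindlist := .N .SD
#' @importFrom stats rnorm rpois runif rgeom median quantile sd setNames
#' @importFrom utils write.csv read.csv
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "chrom", "strand", "pos", "count", "qname", "flag", "rname", "cigar",
  "site_idx", "offset", "score", "site_id", "start0", "ct", "dct", "ddct",
  "condition", "replicate", "amplicon_id", "role", "hk", "fold", "rank_i",
  "w_start", "w_end", "gene_strand", "start1", "N", "q", "w", "dct_base",
  "cut", "cut_fraction", "genic", "gene_id", "mapq", "pnext", "qual",
  "rnext", "tlen", "seq", "site_set"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a GRanges coverage track as bedGraph
#'
#' Emits one line per range in 0-based half-open coordinates
#' (`chrom  start  end  value`), sorted by chromosome then start.
#'
#' @param track a [GenomicRanges::GRanges] with a numeric `score` column.
#' @param path output file path.
#' @param keep_zero keep ranges with score 0 (default drops them).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, keep_zero = FALSE) {
  stopifnot(methods::is(track, "GRanges"), !is.null(track$score))
  if (!keep_zero) track <- track[track$score != 0]
  o <- order(as.character(GenomicRanges::seqnames(track)),
             GenomicRanges::start(track))
  track <- track[o]
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(track)),
    start = GenomicRanges::start(track) - 1L,
    end   = GenomicRanges::end(track),
    value = track$score
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a GRanges track
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @return [GenomicRanges::GRanges] with a `score` metadata column.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr$score <- as.numeric(gr$score)
  gr
}

#' Write gene or site intervals as BED6
#'
#' @param gr GRanges; `name` taken from `gr$name` (or `gr$site_id` /
#'   `gr$gene_id`), strand from `strand(gr)`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(gr, path) {
  nm <- gr$name %||% gr$site_id %||% gr$gene_id %||%
    paste0("feat", seq_along(gr))
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "+"
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    name  = nm,
    score = 0L,
    strand = st
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED6 gene annotation
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return GRanges with `gene_id` metadata column and strand set.
#' @export
read_genes_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand")[1:6])
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = dt$strand,
    gene_id = as.character(dt$name)
  )
}
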