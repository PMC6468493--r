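#' Locate AsiSI recognition sites in a genome
#'
#' Scans every chromosome for the 8-bp AsiSI recognition motif `GCGATCGC`.
#' The motif is its own reverse complement, so a single forward-strand scan
#' reports each cleavable genomic position exactly once — scanning the minus
#' strand would double-count the same loci. Matching is exact and
#' case-insensitive; windows containing `N` (or any ambiguity code) never
#' match.
#'
#' @param genome a [Biostrings::DNAStringSet], a single
#'   [Biostrings::DNAString], or a path to a FASTA file.
#' @param motif recognition sequence (default `"GCGATCGC"`).
#' @return GRanges of sites sorted by (chrom, start), width 8, strand `+`,
#'   with `site_id` and unset annotation columns (`genic`, `gene_id`,
#'   `gene_strand`); see [annotate_sites()].
#' @export
scan_sites <- function(genome, motif = "GCGATCGC") {
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("genome FASTA not found: ", genome)
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (methods::is(genome, "DNAString"))
    genome <- Biostrings::DNAStringSet(list(chr1 = genome))
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0)
    stop("empty genome sequence")
  if (is.null(names(genome)))
    names(genome) <- paste0("chr", seq_along(genome))
  hits <- lapply(names(genome), function(cn) {
    m <- Biostrings::matchPattern(motif, genome[[cn]], fixed = TRUE)
    data.table(chrom = cn, start1 = BiocGenerics::start(m))
  })
  hits <- rbindlist(hits)
  setorder(hits, chrom, start1)
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (nrow(hits) == 0)
    return(GenomicRanges::GRanges(site_id = character(), genic = logical(),
                                  gene_id = character(),
                                  gene_strand = character(),
                                  seqlengths = lens))
  GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = IRanges::IRanges(start = hits$start1, width = nchar(motif)),
    strand = "+",
    site_id = sprintf("site%03d", seq_len(nrow(hits))),
    genic = NA, gene_id = NA_character_, gene_strand = NA_character_,
    seqlengths = lens)
}

#' Annotate sites as genic or intergenic
#'
#' A site is genic iff its 8-bp interval overlaps at least one gene body by
#' >= 1 bp. `gene_id` and `gene_strand` are taken from the overlapping gene.
#' When a site overlaps several genes, the gene with the larger overlap
#' wins; exact ties go to the alphabetically first `gene_id` (a message is
#' emitted). Optionally genes are extended upstream by
#' `promoter_extension` bp so that promoter-proximal sites count as genic.
#'
#' The operation is idempotent and preserves the site count and order.
#'
#' @param sites GRanges from [scan_sites()].
#' @param genes GRanges with `gene_id` and strand (see [read_genes_bed()]).
#' @param promoter_extension bp added upstream of each gene (default 0).
#' @return the input sites with `genic`, `gene_id`, `gene_strand` filled in.
#' @export
annotate_sites <- function(sites, genes, promoter_extension = 0L) {
  stopifnot(methods::is(sites, "GRanges"), methods::is(genes, "GRanges"))
  if (is.null(genes$gene_id)) stop("gene annotation lacks gene_id")
  if (promoter_extension > 0) {
    plus <- as.character(GenomicRanges::strand(genes)) != "-"
    suppressWarnings({
      GenomicRanges::start(genes)[plus] <-
        pmax(1L, GenomicRanges::start(genes)[plus] - promoter_extension)
      GenomicRanges::end(genes)[!plus] <-
        GenomicRanges::end(genes)[!plus] + promoter_extension
    })
    genes <- GenomicRanges::trim(genes)
  }
  sites$genic <- FALSE
  sites$gene_id <- NA_character_
  sites$gene_strand <- NA_character_
  ov <- GenomicRanges::findOverlaps(sites, genes, ignore.strand = TRUE)
  if (length(ov) > 0) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(sites)[qh], GenomicRanges::ranges(genes)[sh]))
    cand <- data.table(q = qh, gene_id = genes$gene_id[sh],
                       gene_strand = as.character(
                         GenomicRanges::strand(genes))[sh],
                       w = w)
    setorder(cand, q, -w, gene_id)  # larger overlap, then alphabetical
    tied <- cand[, .N > 1 && w[1] == w[2], by = q]$V1
    if (any(tied))
      message(sum(tied), " site(s) tie between genes; ",
              "alphabetically first gene_id chosen")
    best <- cand[, .SD[1], by = q]
    sites$genic[best$q] <- TRUE
    sites$gene_id[best$q] <- best$gene_id
    sites$gene_strand[best$q] <- best$gene_strand
  }
  sites
}

#' Export sites as BED6
#'
#' 0-based half-open intervals, `name` = site_id, score 0, strand `+`.
#'
#' @param sites site GRanges.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  sites$name <- sites$site_id
  write_bed6(sites, path)
}
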