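# Shared in-code fixtures (nothing is stored on disk).

# small default-parameter simulation: 40 sites / 20 cut on a 200 kb genome
small_sim <- function(seed = 1L, n_sites = 40L, n_cut = 20L,
                      length_bp = 2e5, ...) {
  simulate_genome(n_chrom = 1L, length_bp = length_bp, n_sites = n_sites,
                  n_cut = n_cut, seed = seed, ...)
}

# write a SAM file for a record table, returning the path
sam_tempfile <- function(records, chrom_lengths) {
  path <- tempfile(fileext = ".sam")
  write_sam(records, chrom_lengths, path)
  path
}

# a strand_profile built directly from a counts data.frame (test injection)
manual_profile <- function(chrom, strand, pos, count = 1L) {
  counts <- data.table::data.table(chrom = chrom, strand = strand,
                                   pos = as.integer(pos),
                                   count = as.integer(count))
  counts <- counts[, .(count = sum(count)), by = .(chrom, strand, pos)]
  data.table::setorder(counts, chrom, strand, pos)
  structure(list(counts = counts, n_pairs_seen = sum(counts$count),
                 n_pairs_accepted = sum(counts$count), n_orphans = 0L,
                 n_cross_ref = 0L),
            class = "strand_profile")
}

# GRanges for a single site given a 0-based start, with host-gene strand
one_site <- function(start0, gene_strand = "+", chrom = "chr1",
                     seqlen = NA_integer_) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, width = 8L),
    strand = "+", site_id = "siteX", genic = !is.na(gene_strand),
    gene_id = ifelse(is.na(gene_strand), NA, "geneX"),
    gene_strand = gene_strand)
  if (!is.na(seqlen))
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(seqlen, chrom)
  gr
}

# constructed Ct table: named shifts per amplicon applied in "treated"
manual_ct_table <- function(shifts, hk_ct = 15, base_ct = 22,
                            replicates = 1L, roles = NULL) {
  amps <- names(shifts)
  roles <- roles %||% stats::setNames(rep("target", length(amps)), amps)
  rows <- list()
  for (cond in c("untreated", "treated")) {
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        amplicon_id = c(amps, "HK1"),
        role = c(unname(roles[amps]), "housekeeping"),
        condition = cond, replicate = r,
        ct = c(base_ct + if (cond == "treated") unlist(shifts) else
          numeric(length(amps)), hk_ct))
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
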