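#' Simulate paired-end mNET-seq alignments
#'
#' Emits properly paired alignment records (FLAG combinations 99/147 and
#' 83/163 only) whose single-nucleotide signal — the 3'-most aligned base of
#' read 2, on the strand of read 1 — follows the generative model used
#' throughout the package:
#'
#' * background pairs: per gene, `Poisson(background_rate * kb)` pairs whose
#'   signal positions are uniform over the gene body, on the gene strand;
#' * induced pairs (only when `induced = TRUE`): per cut site and per strand,
#'   `Poisson(induction_rate * cut_fraction)` pairs whose signal offset
#'   downstream of the site 5' end (gene-oriented) is geometric with mean
#'   `decay_length`, truncated at 2000 bp — emulating bidirectional
#'   break-proximal nascent transcription decaying with distance.
#'
#' The fragment model is deliberately simple: fixed insert 150 bp, read
#' length 50 bp, ungapped `50M` alignments, no duplicates, no quality model.
#' Pairs whose fragments would run off a chromosome end are dropped.
#'
#' @param genome [Biostrings::DNAStringSet] from [simulate_genome()].
#' @param truth matching `sim_truth`.
#' @param genes gene GRanges (background transcription domain).
#' @param induced logical; add DSB-induced break-proximal pairs at cut sites.
#' @param seed integer seed.
#' @return a `data.table` of SAM records (two rows per pair: `qname, flag,
#'   rname, pos, mapq, cigar, rnext, pnext, tlen, seq, qual`), ready for
#'   [write_sam()].
#' @export
simulate_mnet <- function(genome, truth, genes, induced = TRUE, seed = 1L) {
  validate_sim_truth(truth)
  set.seed(seed)
  p <- truth$params
  rl <- p$read_len
  ins <- p$insert_size
  lens <- truth$chrom_lengths

  sig <- list()
  ## background: uniform over gene bodies on the gene strand
  if (length(genes) > 0 && p$background_rate > 0) {
    widths <- GenomicRanges::width(genes)
    n_bg <- rpois(length(genes), p$background_rate * widths / 1000)
    for (gi in seq_along(genes)) {
      if (n_bg[gi] == 0) next
      posv <- GenomicRanges::start(genes)[gi] +
        floor(runif(n_bg[gi], 0, widths[gi]))
      sig[[length(sig) + 1L]] <- data.table(
        chrom = as.character(GenomicRanges::seqnames(genes))[gi],
        pos = as.integer(posv),
        strand = as.character(GenomicRanges::strand(genes))[gi])
    }
  }
  ## induced break-proximal signal at cut sites, both strands
  if (induced) {
    s <- truth$sites
    for (i in which(s$cut)) {
      lambda <- p$induction_rate * s$cut_fraction[i]
      if (lambda <= 0) next
      ## site 5' end in gene orientation; intergenic sites use reference
      fwd <- is.na(s$gene_strand[i]) || s$gene_strand[i] == "+"
      for (str in c("+", "-")) {
        n <- rpois(1, lambda)
        if (n == 0) next
        d <- .rgeom_trunc(n, p$decay_length, 2000L)
        posv <- if (fwd) s$start0[i] + 1L + d else (s$start0[i] + 8L) - d
        sig[[length(sig) + 1L]] <- data.table(
          chrom = s$chrom[i], pos = as.integer(posv), strand = str)
      }
    }
  }
  sig <- if (length(sig)) rbindlist(sig) else
    data.table(chrom = character(), pos = integer(), strand = character())
  ## drop signals whose fragment would leave the chromosome
  keep <- sig$pos - (ins - rl) >= 1L & sig$pos + (ins - rl) <= lens[sig$chrom]
  sig <- sig[keep]
  if (nrow(sig) > 0) {
    sig <- sig[sample.int(nrow(sig))]  # shuffle: streams are unsorted
    sig[, qname := sprintf("pair%06d", seq_len(.N))]
  }
  .records_from_signals(sig, genome, rl, ins)
}

## geometric with mean m, resampled until <= trunc
.rgeom_trunc <- function(n, m, trunc) {
  pr <- 1 / (m + 1)
  d <- rgeom(n, pr)
  while (any(bad <- d > trunc)) d[bad] <- rgeom(sum(bad), pr)
  as.integer(d)
}

## Build the two SAM rows per signal (chrom, pos [1-based], strand).
## '+' signal: read1 forward (99), read2 reverse (147), signal = leftmost
## base of read2.  '-' signal: read1 reverse (83), read2 forward (163),
## signal = rightmost base of read2.
.records_from_signals <- function(sig, genome, rl, ins) {
  empty <- data.table(qname = character(), flag = integer(),
                      rname = character(), pos = integer(), mapq = integer(),
                      cigar = character(), rnext = character(),
                      pnext = integer(), tlen = integer(), seq = character(),
                      qual = character())
  if (nrow(sig) == 0) return(empty)
  cig <- paste0(rl, "M")
  qual <- strrep("I", rl)
  plus <- sig$strand == "+"
  r1_pos <- ifelse(plus, sig$pos - (ins - rl), sig$pos + (ins - 2L * rl) + 1L)
  r2_pos <- ifelse(plus, sig$pos, sig$pos - rl + 1L)
  r1_flag <- ifelse(plus, 99L, 83L)
  r2_flag <- ifelse(plus, 147L, 163L)
  r1_tlen <- ifelse(plus, ins, -ins)
  r2_tlen <- -r1_tlen
  getseq <- function(posv, rc) {
    out <- character(length(posv))
    for (cn in unique(sig$chrom)) {
      idx <- sig$chrom == cn
      v <- Biostrings::Views(genome[[cn]], start = posv[idx], width = rl)
      s <- Biostrings::DNAStringSet(v)
      if (any(rc[idx])) {
        r <- rc[idx]
        s[r] <- Biostrings::reverseComplement(s[r])
      }
      out[idx] <- as.character(s)
    }
    out
  }
  r1 <- data.table(qname = sig$qname, flag = as.integer(r1_flag),
                   rname = sig$chrom, pos = as.integer(r1_pos), mapq = 60L,
                   cigar = cig, rnext = "=", pnext = as.integer(r2_pos),
                   tlen = as.integer(r1_tlen),
                   seq = getseq(r1_pos, !plus), qual = qual)
  r2 <- data.table(qname = sig$qname, flag = as.integer(r2_flag),
                   rname = sig$chrom, pos = as.integer(r2_pos), mapq = 60L,
                   cigar = cig, rnext = "=", pnext = as.integer(r1_pos),
                   tlen = as.integer(r2_tlen),
                   seq = getseq(r2_pos, plus), qual = qual)
  out <- rbindlist(list(r1, r2))
  setorder(out, qname, flag)
  out
}

#' Write simulated alignment records as a SAM file
#'
#' @param records record `data.table` from [simulate_mnet()].
#' @param chrom_lengths named integer vector for the `@SQ` header lines.
#' @param path output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  con <- file(path, "wb")  # binary mode: LF endings, byte-stable output
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(records) > 0)
    writeLines(records[, sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                                 qname, flag, rname, pos, mapq, cigar, rnext,
                                 pnext, tlen, seq, qual)], con)
  invisible(path)
}
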