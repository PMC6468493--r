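#' Proper-pair FLAG filter for mNET-seq pairs
#'
#' Accepts a read pair iff its (read 1, read 2) FLAG combination is exactly
#' (99, 147) or (83, 163) — hexadecimal 0x63/0x93 and 0x53/0xA3 — i.e. a
#' properly paired, primary FR alignment with read 1 on the forward strand
#' (99/147) or the reverse strand (83/163). Unmapped, non-proper, secondary,
#' supplementary and singleton configurations are all rejected.
#'
#' @param flag_read1,flag_read2 integer SAM FLAG values (vectorized).
#' @return logical vector.
#' @export
accept_pair <- function(flag_read1, flag_read2) {
  (flag_read1 == 99L & flag_read2 == 147L) |
    (flag_read1 == 83L & flag_read2 == 163L)
}

#' Single-nucleotide signal position of an accepted pair
#'
#' Implements the mNET-seq single-nucleotide rule: the signal position is
#' the reference coordinate of the 3'-most aligned base of read 2 (its
#' rightmost aligned base when read 2 maps forward, FLAG 163; its leftmost
#' when read 2 maps reverse, FLAG 147), and the signal strand is the strand
#' of read 1 (`+` for FLAG 99, `-` for FLAG 83). In an intact nascent-RNA
#' library this base marks the RNA 3' end protected by RNA polymerase II.
#' The aligned span is CIGAR-aware: only reference-consuming operations
#' (M/D/N/=/X) count, so soft-clipped bases are excluded.
#'
#' @param flag_read1,flag_read2 FLAGs of an accepted pair (vectorized).
#' @param pos_read2 1-based leftmost aligned position of read 2 (SAM POS).
#' @param cigar_read2 CIGAR string of read 2.
#' @return data.frame with `pos` (1-based) and `strand`.
#' @export
pair_signal <- function(flag_read1, flag_read2, pos_read2, cigar_read2) {
  if (!all(accept_pair(flag_read1, flag_read2)))
    stop("pair_signal called on a pair rejected by accept_pair()")
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar_read2)
  fwd2 <- flag_read2 == 163L  # read 2 forward <=> read 1 reverse (83)
  data.frame(
    pos = ifelse(fwd2, pos_read2 + ref_w - 1L, pos_read2),
    strand = ifelse(flag_read1 == 99L, "+", "-")
  )
}

#' Build a strand-specific single-nucleotide 3'-end profile
#'
#' Streams a SAM/BAM file, groups primary records by read name, applies
#' [accept_pair()] and [pair_signal()] to each pair and accumulates
#' per-position counts. No deduplication and no MAPQ filter are applied by
#' default. Pairs whose mates map to different references, and read names
#' without exactly two primary records (orphans), are counted and skipped.
#'
#' @param path SAM or BAM file; need not be sorted.
#' @param min_mapq minimum MAPQ for both mates (default 0 = no filter).
#' @param flip_strand report the opposite of read 1's strand, for libraries
#'   with inverted orientation chemistry (default `FALSE`: read 1's strand,
#'   taken literally).
#' @return a `strand_profile` object: list with `counts` (data.table
#'   `chrom, strand, pos, count`, `pos` 1-based), `n_pairs_seen`,
#'   `n_pairs_accepted`, `n_orphans`, `n_cross_ref`.
#' @export
build_profile <- function(path, min_mapq = 0L, flip_strand = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  tmp <- NULL
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = tmp,
                            indexDestination = FALSE, overwrite = TRUE)
  }
  on.exit(if (!is.null(tmp)) unlink(paste0(tmp, ".bam")))
  ## primary records only; pairing is done here, not by the BAM flags
  flg <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                isSupplementaryAlignment = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      flag = flg,
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar")))[[1]]
  dt <- data.table(qname = res$qname, flag = as.integer(res$flag),
                   rname = as.character(res$rname), pos = res$pos,
                   mapq = res$mapq, cigar = res$cigar)
  new_profile(dt, min_mapq = min_mapq, flip_strand = flip_strand)
}

## core pairing/counting on a record table (shared with tests on in-memory
## simulated records)
new_profile <- function(dt, min_mapq = 0L, flip_strand = FALSE) {
  empty <- data.table(chrom = character(), strand = character(),
                      pos = integer(), count = integer())
  prof <- structure(list(counts = empty, n_pairs_seen = 0L,
                         n_pairs_accepted = 0L, n_orphans = 0L,
                         n_cross_ref = 0L),
                    class = "strand_profile")
  if (nrow(dt) == 0) return(prof)
  dt[, rank_i := (bitwAnd(flag, 0x40L) == 0L)]  # FALSE = first in pair
  cnt <- dt[, .N, by = qname]
  orphans <- cnt[N != 2L, qname]
  prof$n_orphans <- length(orphans)
  dt <- dt[!qname %in% orphans]
  setorder(dt, qname, rank_i)  # read 1 row precedes read 2 row
  if (nrow(dt) == 0) {
    prof$n_pairs_seen <- prof$n_orphans
    return(prof)
  }
  i1 <- seq(1L, nrow(dt), by = 2L)
  pairs <- data.table(
    qname = dt$qname[i1],
    flag1 = dt$flag[i1], flag2 = dt$flag[i1 + 1L],
    rname1 = dt$rname[i1], rname2 = dt$rname[i1 + 1L],
    pos2 = dt$pos[i1 + 1L], cigar2 = dt$cigar[i1 + 1L],
    mapq1 = dt$mapq[i1], mapq2 = dt$mapq[i1 + 1L])
  ## a "pair" whose two records carry the same in-pair rank is malformed
  bad_rank <- dt$rank_i[i1] == dt$rank_i[i1 + 1L]
  prof$n_orphans <- prof$n_orphans + sum(bad_rank)
  pairs <- pairs[!bad_rank]
  prof$n_pairs_seen <- nrow(pairs) + prof$n_orphans
  ok <- accept_pair(pairs$flag1, pairs$flag2)
  if (min_mapq > 0)
    ok <- ok & pairs$mapq1 >= min_mapq & pairs$mapq2 >= min_mapq
  cross <- ok & pairs$rname1 != pairs$rname2
  prof$n_cross_ref <- sum(cross)
  if (prof$n_cross_ref > 0)
    warning(prof$n_cross_ref, " accepted pair(s) with mates on different ",
            "references skipped")
  ok <- ok & !cross
  pairs <- pairs[ok]
  prof$n_pairs_accepted <- nrow(pairs)
  if (nrow(pairs) == 0) return(prof)
  sig <- pair_signal(pairs$flag1, pairs$flag2, pairs$pos2, pairs$cigar2)
  if (flip_strand) sig$strand <- ifelse(sig$strand == "+", "-", "+")
  counts <- data.table(chrom = pairs$rname2, strand = sig$strand,
                       pos = as.integer(sig$pos))[
    , .(count = .N), by = .(chrom, strand, pos)]
  setorder(counts, chrom, strand, pos)
  prof$counts <- counts
  prof
}

#' @export
print.strand_profile <- function(x, ...) {
  cat("strand_profile:", x$n_pairs_accepted, "of", x$n_pairs_seen,
      "pairs accepted;", nrow(x$counts), "non-zero positions\n")
  invisible(x)
}

#' Export one strand of a profile as bedGraph
#'
#' One line per non-zero position as a 0-based half-open 1-bp interval,
#' sorted by (chrom, pos).
#'
#' @param profile `strand_profile` from [build_profile()].
#' @param strand `"+"` or `"-"`.
#' @param path output path.
#' @param negate negate values (conventional for minus-strand tracks).
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(profile, strand, path, negate = FALSE) {
  stopifnot(inherits(profile, "strand_profile"), strand %in% c("+", "-"))
  want <- strand
  dt <- profile$counts[strand == want][, .(chrom, pos, count)]
  setorder(dt, chrom, pos)
  val <- if (negate) -dt$count else dt$count
  out <- data.table(chrom = dt$chrom, start = dt$pos - 1L, end = dt$pos,
                    value = val)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Import a single-strand bedGraph back into a strand_profile
#'
#' Inverse of [export_bedgraph()] for 1-bp interval tracks; used to
#' round-trip profiles through files. Totals are reconstructed from the
#' counts (`n_pairs_seen` cannot be recovered and is set to the sum).
#'
#' @param paths named character vector, e.g. `c("+" = ..., "-" = ...)`.
#' @param negate_minus undo minus-strand negation on import.
#' @return a `strand_profile`.
#' @export
import_bedgraph_profile <- function(paths, negate_minus = FALSE) {
  stopifnot(!is.null(names(paths)), all(names(paths) %in% c("+", "-")))
  parts <- lapply(names(paths), function(s) {
    if (file.size(paths[[s]]) == 0)
      return(data.table(chrom = character(), strand = character(),
                        pos = integer(), count = integer()))
    dt <- data.table::fread(paths[[s]], header = FALSE,
                            col.names = c("chrom", "start", "end", "value"))
    if (nrow(dt) > 0 && any(dt$end - dt$start != 1L))
      stop("not a single-nucleotide bedGraph: ", paths[[s]])
    v <- dt$value
    if (s == "-" && negate_minus) v <- -v
    data.table(chrom = dt$chrom, strand = s, pos = dt$start + 1L,
               count = as.integer(v))
  })
  counts <- rbindlist(parts)
  setorder(counts, chrom, strand, pos)
  structure(list(counts = counts,
                 n_pairs_seen = sum(counts$count),
                 n_pairs_accepted = sum(counts$count),
                 n_orphans = 0L, n_cross_ref = 0L),
            class = "strand_profile")
}
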