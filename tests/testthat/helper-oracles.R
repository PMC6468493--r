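# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no Biostrings matching, no Rsamtools, no shared CIGAR helper)
# so that agreement is evidence of correctness, not of shared bugs.

# exhaustive 8-mer-window motif scan; returns 1-based start positions
bf_scan <- function(seq_string, motif = "GCGATCGC") {
  n <- nchar(seq_string)
  k <- nchar(motif)
  if (n < k) return(integer(0))
  wins <- substring(seq_string, 1:(n - k + 1), k:n)
  which(wins == motif)
}

# reference-consumed width from a CIGAR string, by regex
bf_cigar_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

# brute-force single-nucleotide 3'-end extraction from a SAM file:
# group lines by read name, keep FLAG pairs (99,147)/(83,163), apply the
# "3'-most base of read 2, strand of read 1" rule
bf_profile <- function(sam_path) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  out <- list(chrom = character(0), strand = character(0), pos = integer(0))
  if (length(lines) > 0) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    qn <- vapply(fields, `[[`, "", 1)
    for (grp in split(fields, qn)) {
      if (length(grp) != 2) next
      flags <- vapply(grp, function(f) as.integer(f[[2]]), 0L)
      r1 <- grp[[which(bitwAnd(flags, 64L) != 0L)[1]]]
      r2 <- grp[[which(bitwAnd(flags, 128L) != 0L)[1]]]
      if (length(which(bitwAnd(flags, 64L) != 0L)) != 1) next
      f1 <- as.integer(r1[[2]]); f2 <- as.integer(r2[[2]])
      okpair <- (f1 == 99L && f2 == 147L) || (f1 == 83L && f2 == 163L)
      if (!okpair) next
      if (r1[[3]] != r2[[3]]) next
      p2 <- as.integer(r2[[4]])
      pos <- if (f2 == 163L) p2 + bf_cigar_width(r2[[6]]) - 1L else p2
      out$chrom <- c(out$chrom, r2[[3]])
      out$strand <- c(out$strand, if (f1 == 99L) "+" else "-")
      out$pos <- c(out$pos, pos)
    }
  }
  df <- as.data.frame(table(chrom = out$chrom, strand = out$strand,
                            pos = out$pos), stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, ]
  df$pos <- as.integer(df$pos)
  df <- df[order(df$chrom, df$strand, df$pos), ]
  data.frame(chrom = df$chrom, strand = df$strand, pos = df$pos,
             count = as.integer(df$Freq), row.names = NULL)
}

# hand-computed ddCt spreadsheet: one amplicon, one housekeeping reference
# value per (condition, replicate); folds averaged over replicates
bf_ddct_percent <- function(ct_amp, ct_hk_untreated, ct_hk_treated) {
  dct_u <- ct_amp$untreated - ct_hk_untreated
  dct_t <- ct_amp$treated - ct_hk_treated
  folds <- 2^(-(dct_t - dct_u))
  (1 - mean(folds)) * 100
}
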