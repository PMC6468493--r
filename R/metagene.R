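#' Per-site signal matrix around site 5' ends, gene-oriented
#'
#' Collects single-nucleotide 3'-end counts into a per-site x per-offset
#' matrix over offsets `-flank .. +flank`, where offset 0 is the 5' end of
#' the 8-bp site *in the orientation of the host gene*:
#'
#' * `+` strand host gene: `offset = pos - site_start`; sense counts come
#'   from the `+` profile strand, antisense from `-`;
#' * `-` strand host gene: the frame is flipped, `offset = site_end - pos`
#'   (1-based inclusive coordinates), sense counts come from `-`, antisense
#'   from `+`.
#'
#' This gene-oriented frame lets sites hosted on either strand average
#' coherently. With `orientation = "reference"` every site uses the `+`
#' frame regardless of annotation (for intergenic site sets).
#'
#' Sites whose window `site 5' end +/- flank` exceeds the chromosome bounds
#' are dropped with a message rather than zero-padded. Signal falling in the
#' windows of several (overlapping) sites is counted once per site.
#'
#' @param profile `strand_profile` from [build_profile()].
#' @param sites site GRanges; needs `gene_strand` unless
#'   `orientation = "reference"`.
#' @param flank window half-width in bp (default 2000).
#' @param orientation `"gene"` (default) or `"reference"`.
#' @return a `metagene_matrix`: list with `offsets` (`-flank..flank`),
#'   `sense` and `antisense` (site x offset matrices) and `site_ids`.
#' @export
site_matrix <- function(profile, sites, flank = 2000L,
                        orientation = c("gene", "reference")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(profile, "strand_profile"), methods::is(sites, "GRanges"))
  if (length(sites) == 0) stop("empty site list")
  gstrand <- if (orientation == "reference") rep("+", length(sites)) else
    as.character(sites$gene_strand)
  if (orientation == "gene" && anyNA(gstrand))
    stop("site(s) without gene_strand; annotate sites or use ",
         'orientation = "reference"')
  ## anchor = gene-oriented 5' end of the site (1-based)
  anchor <- ifelse(gstrand == "+", GenomicRanges::start(sites),
                   GenomicRanges::end(sites))
  chromv <- as.character(GenomicRanges::seqnames(sites))
  keep <- anchor - flank >= 1L
  sl <- GenomeInfoDb::seqlengths(sites)
  if (!all(is.na(sl))) {
    lens <- sl[chromv]
    keep <- keep & (is.na(lens) | anchor + flank <= lens)
  }
  if (any(!keep))
    message(sum(!keep), " site(s) dropped: window exceeds chromosome bounds")
  if (!any(keep)) stop("no site window fits inside the genome")
  sites <- sites[keep]
  anchor <- anchor[keep]
  gstrand <- gstrand[keep]
  chromv <- chromv[keep]
  ids <- sites$site_id %||% paste0("site", seq_along(sites))

  L <- 2L * flank + 1L
  sense <- matrix(0, nrow = length(sites), ncol = L,
                  dimnames = list(ids, NULL))
  antisense <- matrix(0, nrow = length(sites), ncol = L,
                      dimnames = list(ids, NULL))
  cnt <- profile$counts
  if (nrow(cnt) > 0) {
    wins <- data.table(site_idx = seq_along(sites), chrom = chromv,
                       w_start = anchor - flank, w_end = anchor + flank,
                       anchor = anchor, gs = gstrand)
    setkey(wins, chrom, w_start, w_end)
    hits <- data.table::foverlaps(
      cnt[, .(chrom, strand, pos, count, start = pos, end = pos)],
      wins, by.x = c("chrom", "start", "end"), nomatch = NULL)
    if (nrow(hits) > 0) {
      off <- ifelse(hits$gs == "+", hits$pos - hits$anchor,
                    hits$anchor - hits$pos)
      col <- off + flank + 1L
      is_sense <- hits$strand == hits$gs
      idx_s <- cbind(hits$site_idx[is_sense], col[is_sense])
      idx_a <- cbind(hits$site_idx[!is_sense], col[!is_sense])
      ## aggregate duplicates before assignment
      add_to <- function(m, idx, val) {
        if (nrow(idx) == 0) return(m)
        key <- paste(idx[, 1], idx[, 2])
        agg <- tapply(val, key, sum)
        ij <- do.call(rbind, strsplit(names(agg), " "))
        m[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] <-
          m[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] + as.numeric(agg)
        m
      }
      sense <- add_to(sense, idx_s, hits$count[is_sense])
      antisense <- add_to(antisense, idx_a, hits$count[!is_sense])
    }
  }
  structure(list(offsets = seq(-flank, flank), sense = sense,
                 antisense = antisense, site_ids = ids, flank = flank),
            class = "metagene_matrix")
}

#' Average a metagene matrix into a profile
#'
#' Per-offset arithmetic mean across sites, separately for the sense and
#' antisense orientations.
#'
#' @param matrix a `metagene_matrix` from [site_matrix()].
#' @return a `metagene_profile`: list with `offsets`, `mean_sense`,
#'   `mean_antisense`, `smoothed = FALSE`, `n_sites`.
#' @export
average_profile <- function(matrix) {
  stopifnot(inherits(matrix, "metagene_matrix"), nrow(matrix$sense) > 0)
  structure(list(offsets = matrix$offsets,
                 mean_sense = colMeans(matrix$sense),
                 mean_antisense = colMeans(matrix$antisense),
                 smoothed = FALSE, n_sites = nrow(matrix$sense)),
            class = "metagene_profile")
}

#' Forward rolling-average smoothing
#'
#' Replaces each value by the mean of the forward-looking window
#' `[x, x + window - 1]` (the classic 5-nt rolling average uses
#' `window = 5`). At the right edge, where fewer than `window` positions
#' remain, the mean is taken over the available positions, so the last
#' position is returned unchanged. Constant vectors are invariant.
#'
#' @param profile a `metagene_profile` (or a bare numeric vector).
#' @param window window size in nt (default 5).
#' @return the smoothed profile (or vector).
#' @export
rolling_smooth <- function(profile, window = 5L) {
  stopifnot(window >= 1)
  roll <- function(x) as.numeric(
    zoo::rollapply(x, width = window, FUN = mean, align = "left",
                   partial = TRUE))
  if (is.numeric(profile)) return(roll(profile))
  stopifnot(inherits(profile, "metagene_profile"))
  profile$mean_sense <- roll(profile$mean_sense)
  profile$mean_antisense <- roll(profile$mean_antisense)
  profile$smoothed <- TRUE
  profile
}

#' Proximal/distal break-transcription statistic
#'
#' For each site, the combined (sense + antisense) 3'-end signal summed over
#' a proximal downstream window (default offsets `[0, 500)`) is divided by
#' the sum over a distal downstream window (default `[1500, 2000)`), with a
#' pseudocount guarding empty windows:
#' `ratio = (proximal + p) / (distal + p)`. Break-induced transcription is
#' proximal to the cut, so cut sites show elevated ratios relative to uncut
#' sites or uninduced conditions. With `symmetric = TRUE` both windows are
#' mirrored around the site (`[-500, 500)` etc.).
#'
#' @param matrix a `metagene_matrix`.
#' @param proximal,distal half-open offset windows `c(from, to)`.
#' @param pseudocount added to numerator and denominator (default 1).
#' @param symmetric also include the mirrored upstream windows.
#' @return list with `per_site` (data.frame `site_id, proximal, distal,
#'   ratio`) and `summary` (median and quartiles of the ratios).
#' @export
proximal_distal_stat <- function(matrix, proximal = c(0L, 500L),
                                 distal = c(1500L, 2000L), pseudocount = 1.0,
                                 symmetric = FALSE) {
  stopifnot(inherits(matrix, "metagene_matrix"))
  F <- matrix$flank
  win_sum <- function(win) {
    stopifnot(win[1] >= -F, win[2] <= F + 1L)
    cols <- (win[1] + F + 1L):(win[2] + F)  # half-open [from, to)
    if (symmetric) cols <- c((-win[2] + F + 1L):(-win[1] + F), cols)
    rowSums(matrix$sense[, cols, drop = FALSE]) +
      rowSums(matrix$antisense[, cols, drop = FALSE])
  }
  pr <- win_sum(proximal)
  di <- win_sum(distal)
  ratio <- (pr + pseudocount) / (di + pseudocount)
  qs <- quantile(ratio, c(0.25, 0.5, 0.75), names = FALSE)
  list(per_site = data.frame(site_id = matrix$site_ids, proximal = pr,
                             distal = di, ratio = ratio,
                             row.names = NULL),
       summary = data.frame(n_sites = length(ratio), q1 = qs[1],
                            median = qs[2], q3 = qs[3]))
}

#' Write a metagene profile as TSV
#'
#' @param profile `metagene_profile`.
#' @param path output TSV (`offset, sense, antisense`).
#' @return `path`, invisibly.
#' @export
write_metagene_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "metagene_profile"))
  data.table::fwrite(data.table(offset = profile$offsets,
                                sense = profile$mean_sense,
                                antisense = profile$mean_antisense),
                     path, sep = "\t")
  invisible(path)
}
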