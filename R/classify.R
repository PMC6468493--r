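#' Counts-per-million normalization of a coverage track
#'
#' Scales a binned coverage track so that its total mass — the sum of
#' `score * width_bp` over all ranges — equals 10^6. Normalizing both the
#' damage-mark treatment track and its control to CPM before forming log2
#' ratios removes library-size differences. The operation is idempotent on a
#' track whose total is already 10^6.
#'
#' @param track GRanges with a numeric `score`.
#' @return the track with `score` rescaled.
#' @export
normalize_cpm <- function(track) {
  stopifnot(methods::is(track, "GRanges"), !is.null(track$score))
  total <- sum(as.numeric(track$score) * GenomicRanges::width(track))
  if (!is.finite(total) || total <= 0)
    stop("cannot CPM-normalize a track with non-positive total")
  track$score <- track$score * 1e6 / total
  track
}

#' Damage log2 ratio of a site window
#'
#' The per-site damage score is `log2((T + p) / (C + p))` where `T` and `C`
#' are the mean per-bp CPM of the treatment (e.g. gammaH2A.X) and control
#' (e.g. H2A.X) tracks over the window `[site_start - window_bp,
#' site_end + window_bp)`. The pseudocount `p` (default 1 CPM) guards empty
#' windows. Windows running off a chromosome end are truncated (with a
#' message).
#'
#' @param sites site GRanges (from [scan_sites()] / [annotate_sites()]).
#' @param treatment,control CPM-normalized GRanges tracks
#'   (see [normalize_cpm()]).
#' @param window_bp flank added on each side of the 8-bp site (default 1000).
#' @param pseudocount added to both means (default 1).
#' @return numeric vector of log2 ratios, one per site.
#' @export
site_log2_score <- function(sites, treatment, control, window_bp = 1000L,
                            pseudocount = 1.0) {
  stopifnot(methods::is(sites, "GRanges"))
  win <- suppressWarnings(
    GenomicRanges::resize(sites, GenomicRanges::width(sites) + 2L * window_bp,
                          fix = "center"))
  clipped <- GenomicRanges::start(win) < 1L
  sl <- GenomeInfoDb::seqlengths(win)
  if (!all(is.na(sl))) {
    lens <- sl[as.character(GenomicRanges::seqnames(win))]
    clipped <- clipped | (!is.na(lens) & GenomicRanges::end(win) > lens)
  }
  if (any(clipped))
    message(sum(clipped), " site window(s) truncated at chromosome bounds")
  GenomicRanges::start(win) <- pmax(1L, GenomicRanges::start(win))
  win <- GenomicRanges::trim(win)
  tmean <- .window_mean(win, treatment)
  cmean <- .window_mean(win, control)
  log2((tmean + pseudocount) / (cmean + pseudocount))
}

## mean per-bp track value over each window (missing ranges count as 0)
.window_mean <- function(win, track) {
  ov <- GenomicRanges::findOverlaps(win, track, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(win)[qh], GenomicRanges::ranges(track)[sh]))
  mass <- tapply(as.numeric(track$score[sh]) * w, qh, sum)
  out <- numeric(length(win))
  out[as.integer(names(mass))] <- mass
  out / GenomicRanges::width(win)
}

#' Score sites and select the cut and uncut sets
#'
#' `score_sites()` computes a per-site score table; `select_cut_uncut()` labels
#' the `n` highest-scoring eligible sites "cut" and the `n` lowest-scoring
#' "uncut" (the negative-control set), mirroring the selection of the most
#' and least efficiently restricted genic sites. All eligible sites are
#' ranked once by decreasing score with ties broken by (chrom, start)
#' ascending; cut = ranks `1..n`, uncut = the `n` largest ranks, so the two
#' sets are disjoint whenever `>= 2n` sites are eligible (fewer is an
#' error).
#'
#' @param sites annotated site GRanges.
#' @param treatment,control coverage tracks (raw; CPM applied internally).
#' @param window_bp,pseudocount see [site_log2_score()].
#' @return `score_sites()`: a data.frame `site_id, chrom, start0, genic,
#'   log2_ratio, rank, label` with `label = "unlabelled"`; ranks permute
#'   `1..n` over scored sites.
#' @export
score_sites <- function(sites, treatment, control, window_bp = 1000L,
                        pseudocount = 1.0) {
  lr <- site_log2_score(sites, normalize_cpm(treatment),
                        normalize_cpm(control),
                        window_bp = window_bp, pseudocount = pseudocount)
  df <- data.table(
    site_id = sites$site_id,
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start0 = GenomicRanges::start(sites) - 1L,
    genic = if (is.null(sites$genic)) NA else as.logical(sites$genic),
    log2_ratio = lr)
  ord <- order(-df$log2_ratio, df$chrom, df$start0)
  df$rank <- integer(nrow(df))
  df$rank[ord] <- seq_len(nrow(df))
  df$label <- "unlabelled"
  setorder(df, chrom, start0)
  as.data.frame(df)
}

#' @rdname score_sites
#' @param scores SiteScore data.frame from [score_sites()].
#' @param n size of each label set (the reference analysis uses 94).
#' @param genic_only restrict eligibility to genic sites (default TRUE).
#' @return `select_cut_uncut()`: list with `cut` and `uncut` site_id
#'   vectors and `scores`, the table with labels written back.
#' @export
select_cut_uncut <- function(scores, n = 94L, genic_only = TRUE) {
  elig <- scores
  if (genic_only) {
    if (all(is.na(elig$genic)))
      stop("genic_only = TRUE but sites are unannotated")
    elig <- elig[!is.na(elig$genic) & elig$genic, , drop = FALSE]
  }
  if (nrow(elig) < 2L * n)
    stop("need at least ", 2L * n, " eligible sites to label ", n,
         " cut + ", n, " uncut; only ", nrow(elig), " available")
  ord <- order(-elig$log2_ratio, elig$chrom, elig$start0)
  cut_ids <- elig$site_id[ord[seq_len(n)]]
  uncut_ids <- elig$site_id[ord[seq(nrow(elig) - n + 1L, nrow(elig))]]
  scores$label[scores$site_id %in% cut_ids] <- "cut"
  scores$label[scores$site_id %in% uncut_ids] <- "uncut"
  list(cut = cut_ids, uncut = uncut_ids, scores = scores)
}
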