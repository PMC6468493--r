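#' Simulate damage-mark ChIP coverage tracks
#'
#' Produces a binned treatment (e.g. gammaH2A.X) and control (e.g. total
#' H2A.X) coverage track pair. The control is flat Poisson noise with mean
#' `depth` counts per bin; the treatment adds, around each *cut* site only, a
#' boxcar of half-width `chip_spread` and amplitude
#' `(chip_enrichment - 1) * depth`, i.e. the expected treatment/control
#' ratio inside the window is `chip_enrichment` and 1 elsewhere. Uncut sites
#' receive no enrichment.
#'
#' @param truth `sim_truth` from [simulate_genome()].
#' @param depth expected control counts per bin (sequencing depth proxy).
#' @param seed integer seed.
#' @param bin_width bp per bin (default 50).
#' @return list of two GRanges tracks, `treatment` and `control`, each with
#'   a `score` column (raw counts; see [normalize_cpm()]).
#' @export
simulate_chip <- function(truth, depth = 50, seed = 1L, bin_width = 50L) {
  validate_sim_truth(truth)
  stopifnot(depth > 0)
  set.seed(seed)
  p <- truth$params
  grl <- lapply(names(truth$chrom_lengths), function(cn) {
    len <- truth$chrom_lengths[[cn]]
    starts <- seq(1L, len, by = bin_width)
    ends <- pmin(starts + bin_width - 1L, len)
    mid <- (starts + ends) / 2
    rate_t <- rep(depth, length(starts))
    s <- truth$sites[chrom == cn & cut == TRUE]
    if (nrow(s) > 0) {
      centre <- s$start0 + 4.5  # site midpoint, 1-based
      for (cmid in centre) {
        inside <- abs(mid - cmid) <= p$chip_spread
        rate_t[inside] <- rate_t[inside] + (p$chip_enrichment - 1) * depth
      }
    }
    GenomicRanges::GRanges(
      seqnames = cn,
      ranges = IRanges::IRanges(start = starts, end = ends),
      treatment = rpois(length(starts), rate_t),
      control = rpois(length(starts), depth),
      seqlengths = truth$chrom_lengths)
  })
  gr <- suppressWarnings(do.call(c, grl))
  tr <- gr
  tr$score <- as.numeric(tr$treatment)
  tr$treatment <- tr$control <- NULL
  co <- gr
  co$score <- as.numeric(co$control)
  co$treatment <- co$control <- NULL
  list(treatment = tr, control = co)
}
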