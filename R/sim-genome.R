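#' Simulate a toy genome with planted AsiSI sites and gene models
#'
#' Generates a uniformly random A/C/G/T genome in which the 8-bp AsiSI
#' recognition motif `GCGATCGC` occurs at exactly the planted positions and
#' nowhere else: spontaneous occurrences of the (palindromic) motif are
#' destroyed by single-base substitution and the sequence re-scanned until
#' clean. Non-overlapping gene intervals with random strand are laid down so
#' that every genic site is contained in exactly one gene. A subset of sites
#' is flagged as "cut" with a per-site cut fraction; these flags are the
#' ground truth against which ChIP-based classification and qPCR-based %DSB
#' quantitation are tested downstream.
#'
#' Each chromosome has length `length_bp`. Sites are packed into disjoint
#' 4 kb slots inside a `flank_margin` (default 2000 bp) from either
#' chromosome end, which guarantees pairwise non-overlap and full metagene
#' windows; packing that cannot satisfy these constraints is an error.
#'
#' @param n_chrom number of chromosomes (each of length `length_bp`).
#' @param length_bp chromosome length in bp; must allow 4000 bp per site.
#' @param n_sites number of planted AsiSI sites (>= 1).
#' @param n_genes number of genes; the first `min(n_genes, n_sites)` sites
#'   (in random order) become genic, remaining sites are intergenic. Extra
#'   genes beyond `n_sites` are placed in site-free gaps.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param n_cut number of sites flagged cut (default half, rounded down).
#' @param cut_fraction per-cut-site fraction of alleles cleaved, scalar or
#'   length-`n_cut` vector in \[0, 1).
#' @param induction_rate expected DSB-induced read pairs per cut site and
#'   strand under induction.
#' @param decay_length bp scale of the geometric decay of break-proximal
#'   signal (default 250 bp, truncated at 2000 bp downstream).
#' @param background_rate background read pairs per kb of gene body.
#' @param chip_enrichment fold enrichment of the damage-mark ChIP treatment
#'   track over control at cut sites.
#' @param chip_spread bp half-width of the ChIP enrichment boxcar.
#' @param ct_noise_sd qPCR Ct measurement noise, in cycles.
#' @param flank_margin minimum bp between any site and a chromosome end.
#' @return a list with elements `genome` ([Biostrings::DNAStringSet]),
#'   `truth` (a `sim_truth` object, see [validate_sim_truth()]) and `genes`
#'   (a [GenomicRanges::GRanges] with `gene_id`).
#' @export
simulate_genome <- function(n_chrom = 1L, length_bp, n_sites, n_genes = n_sites,
                            seed = 1L, n_cut = floor(n_sites / 2),
                            cut_fraction = 0.8, induction_rate = 200,
                            decay_length = 250, background_rate = 2,
                            chip_enrichment = 8, chip_spread = 2000,
                            ct_noise_sd = 0.1, flank_margin = 2000L) {
  stopifnot(n_sites >= 1, n_chrom >= 1, length_bp >= 1)
  slot <- 4000L
  if (as.double(n_sites) * slot > as.double(n_chrom) * length_bp)
    stop("infeasible packing: ", n_sites, " sites need ", n_sites * slot,
         " bp but the genome has ", n_chrom * length_bp, " bp")
  usable <- length_bp - 2L * flank_margin - 8L
  cap_per_chrom <- max(0L, usable %/% slot)
  if (cap_per_chrom * n_chrom < n_sites)
    stop("infeasible packing: at most ", cap_per_chrom, " site(s) fit per ",
         length_bp, " bp chromosome with a ", flank_margin,
         " bp flank margin; cannot place ", n_sites)
  set.seed(seed)
  motif <- "GCGATCGC"
  chroms <- paste0("chr", seq_len(n_chrom))
  chrom_lengths <- setNames(rep(as.integer(length_bp), n_chrom), chroms)

  ## assign sites to chromosomes, then to disjoint slots within each
  per_chrom <- rep(n_sites %/% n_chrom, n_chrom)
  extra <- n_sites %% n_chrom
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  site_list <- list()
  slot_list <- list()
  for (ci in seq_len(n_chrom)) {
    k <- per_chrom[ci]
    if (k == 0) next
    w <- usable %/% k
    slot_start <- flank_margin + 1L + (seq_len(k) - 1L) * w
    ## jitter around slot centres, bounded so that consecutive sites stay
    ## >= chip_spread + 1200 bp apart: the enrichment domain of one site
    ## never overlaps the damage-score window of its neighbour
    min_gap <- chip_spread + 1200
    jit <- floor(max(0, w - min_gap) / 2)
    centre <- slot_start + (w - 8L) %/% 2L
    start1 <- centre + floor(runif(k, min = -jit, max = jit + 1))
    site_list[[ci]] <- data.table(chrom = chroms[ci],
                                  start1 = as.integer(start1))
    slot_list[[ci]] <- data.table(chrom = chroms[ci],
                                  lo = as.integer(slot_start),
                                  hi = as.integer(slot_start + w - 1L))
  }
  sites <- rbindlist(site_list)
  slots <- rbindlist(slot_list)
  setorder(sites, chrom, start1)
  setorder(slots, chrom, lo)
  sites[, site_id := sprintf("site%03d", seq_len(.N))]

  ## random genome, spontaneous motifs destroyed, truth motifs planted
  seqs <- lapply(chroms, function(cn) {
    x <- Biostrings::DNAString(paste(
      sample(c("A", "C", "G", "T"), length_bp, replace = TRUE),
      collapse = ""))
    planted <- sites[chrom == cn, start1]
    x <- .plant_exactly(x, planted, motif)
    x
  })
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms

  ## gene models: one gene around each genic site, inside its slot
  n_genic <- min(n_genes, n_sites)
  genic_idx <- sort(sample.int(n_sites, n_genic))
  sites[, `:=`(genic = FALSE, gene_id = NA_character_,
               gene_strand = NA_character_)]
  gene_rows <- list()
  for (j in seq_along(genic_idx)) {
    i <- genic_idx[j]
    gid <- sprintf("gene%03d", j)
    s1 <- sites$start1[i]
    sl <- slots[i]  # slots and sites share (chrom, start) order
    up <- floor(runif(1, 1000, 2500))
    dn <- floor(runif(1, 1000, 2500))
    gstart <- max(sl$lo, s1 - up)
    gend <- min(sl$hi, s1 + 7L + dn)
    gstrand <- sample(c("+", "-"), 1)
    sites[i, `:=`(genic = TRUE, gene_id = gid, gene_strand = gstrand)]
    gene_rows[[j]] <- data.table(chrom = sites$chrom[i],
                                 start1 = as.integer(gstart),
                                 end1 = as.integer(gend),
                                 gene_id = gid, strand = gstrand)
  }
  genes <- rbindlist(gene_rows)
  n_extra <- n_genes - n_genic
  if (n_extra > 0) {
    ## site-free genes go into the right flank margins, one per chromosome
    if (n_extra > n_chrom || flank_margin < 1600L)
      stop("infeasible packing: no room for ", n_extra, " site-free gene(s)")
    for (j in seq_len(n_extra)) {
      cn <- chroms[j]
      gene_rows[[n_genic + j]] <- data.table(
        chrom = cn, start1 = as.integer(length_bp - flank_margin + 100L),
        end1 = as.integer(length_bp - 100L),
        gene_id = sprintf("gene%03d", n_genic + j),
        strand = sample(c("+", "-"), 1))
    }
    genes <- rbindlist(gene_rows)
  }

  ## cut flags and fractions
  stopifnot(n_cut >= 0, n_cut <= n_sites)
  cut_idx <- if (n_cut > 0) sort(sample.int(n_sites, n_cut)) else integer(0)
  sites[, cut := FALSE][cut_idx, cut := TRUE]
  cf <- rep(0, n_sites)
  cut_fraction <- rep_len(cut_fraction, length(cut_idx))
  if (any(cut_fraction < 0 | cut_fraction >= 1))
    stop("cut_fraction must lie in [0, 1)")
  cf[cut_idx] <- cut_fraction
  sites[, cut_fraction := cf]
  sites[, start0 := start1 - 1L]

  truth <- structure(list(
    seed = as.integer(seed),
    chrom_lengths = chrom_lengths,
    sites = sites[, .(site_id, chrom, start0, genic, gene_id, gene_strand,
                      cut, cut_fraction)],
    params = list(induction_rate = induction_rate,
                  decay_length = decay_length,
                  background_rate = background_rate,
                  chip_enrichment = chip_enrichment,
                  chip_spread = chip_spread,
                  ct_noise_sd = ct_noise_sd,
                  flank_margin = as.integer(flank_margin),
                  read_len = 50L, insert_size = 150L)
  ), class = "sim_truth")
  validate_sim_truth(truth)

  genes_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start1, end = genes$end1),
    strand = genes$strand, gene_id = genes$gene_id,
    seqlengths = chrom_lengths)
  list(genome = genome, truth = truth, genes = genes_gr)
}

## Plant `motif` at the given 1-based starts of DNAString `x` and destroy
## every other occurrence by single-base substitution, re-scanning until the
## motif occurs at exactly the planted positions.
.plant_exactly <- function(x, planted, motif) {
  bases <- c("A", "C", "G", "T")
  protect <- IRanges::IRanges(start = planted, width = nchar(motif))
  for (p in planted)
    Biostrings::subseq(x, start = p, width = nchar(motif)) <-
      Biostrings::DNAString(motif)
  repeat {
    hits <- Biostrings::matchPattern(motif, x)
    extra <- setdiff(BiocGenerics::start(hits), planted)
    if (length(extra) == 0) break
    for (s in extra) {
      cand <- s:(s + nchar(motif) - 1L)
      inside <- IRanges::overlapsAny(
        IRanges::IRanges(start = cand, width = 1L), protect)
      cand <- cand[!inside]  # never touch a planted site
      p <- cand[sample.int(length(cand), 1)]
      old <- as.character(Biostrings::subseq(x, start = p, width = 1L))
      Biostrings::subseq(x, start = p, width = 1L) <-
        Biostrings::DNAString(sample(setdiff(bases, old), 1))
    }
  }
  x
}

#' Validate a sim_truth object
#'
#' Checks the ground-truth invariants: every site keeps at least the flank
#' margin to its chromosome ends, sites are pairwise non-overlapping, and
#' `cut_fraction` is 0 exactly where the cut flag is FALSE.
#'
#' @param truth a `sim_truth` object from [simulate_genome()].
#' @return `truth`, invisibly; errors if an invariant is violated.
#' @export
validate_sim_truth <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  s <- truth$sites
  fm <- truth$params$flank_margin
  len <- truth$chrom_lengths[s$chrom]
  if (any(s$start0 < fm) || any(s$start0 + 8L > len - fm))
    stop("sim_truth invariant violated: site within flank margin of a ",
         "chromosome end")
  by_chrom <- split(s$start0, s$chrom)
  for (v in by_chrom)
    if (length(v) > 1 && any(diff(sort(v)) < 8L))
      stop("sim_truth invariant violated: overlapping sites")
  if (any(!s$cut & s$cut_fraction != 0))
    stop("sim_truth invariant violated: cut_fraction nonzero at uncut site")
  if (any(s$cut_fraction < 0 | s$cut_fraction >= 1))
    stop("sim_truth invariant violated: cut_fraction outside [0, 1)")
  invisible(truth)
}

#' Ground-truth sites as GRanges
#'
#' @param truth a `sim_truth` object.
#' @return GRanges of the planted 8-bp sites with `site_id`, `genic`,
#'   `gene_id`, `gene_strand`, `cut` and `cut_fraction` metadata.
#' @export
truth_sites <- function(truth) {
  s <- truth$sites
  GenomicRanges::GRanges(
    seqnames = s$chrom,
    ranges = IRanges::IRanges(start = s$start0 + 1L, width = 8L),
    strand = "+",
    site_id = s$site_id, genic = s$genic, gene_id = s$gene_id,
    gene_strand = s$gene_strand, cut = s$cut, cut_fraction = s$cut_fraction,
    seqlengths = truth$chrom_lengths)
}

#' Write / read a sim_truth JSON sidecar
#'
#' @param truth a `sim_truth` object.
#' @param path JSON file path.
#' @return `path` invisibly (write); a `sim_truth` (read).
#' @export
write_sim_truth <- function(truth, path) {
  obj <- list(seed = truth$seed,
              chrom_lengths = as.list(truth$chrom_lengths),
              sites = truth$sites, params = truth$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- structure(list(
    seed = as.integer(obj$seed),
    chrom_lengths = unlist(obj$chrom_lengths),
    sites = data.table::as.data.table(obj$sites),
    params = obj$params), class = "sim_truth")
  validate_sim_truth(truth)
}
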