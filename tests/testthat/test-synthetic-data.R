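test_that("identical seeds reproduce genome, truth and reads byte-identically", {
  a <- simulate_genome(n_chrom = 2, length_bp = 3e4, n_sites = 4, seed = 7)
  b <- simulate_genome(n_chrom = 2, length_bp = 3e4, n_sites = 4, seed = 7)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$sites, b$truth$sites)
  expect_identical(as.data.frame(a$genes), as.data.frame(b$genes))
  ra <- simulate_mnet(a$genome, a$truth, a$genes, induced = TRUE, seed = 3)
  rb <- simulate_mnet(b$genome, b$truth, b$genes, induced = TRUE, seed = 3)
  expect_identical(ra, rb)
  ca <- simulate_chip(a$truth, depth = 20, seed = 5)
  cb <- simulate_chip(b$truth, depth = 20, seed = 5)
  expect_identical(ca$treatment$score, cb$treatment$score)
  ta <- simulate_ct(a$truth, seed = 2)
  tb <- simulate_ct(b$truth, seed = 2)
  expect_identical(ta, tb)
})

test_that("planted motifs are the only motif occurrences (brute-force scan)", {
  sim1 <- simulate_genome(n_chrom = 1, length_bp = 1e4, n_sites = 1, seed = 7)
  hits <- bf_scan(as.character(sim1$genome[[1]]))
  expect_identical(hits, sim1$truth$sites$start0 + 1L)
  sim5 <- simulate_genome(n_chrom = 1, length_bp = 4e4, n_sites = 5, seed = 11)
  hits5 <- bf_scan(as.character(sim5$genome[[1]]))
  expect_identical(hits5, sim5$truth$sites$start0 + 1L)
})

test_that("infeasible site packing is an explicit error", {
  expect_error(simulate_genome(n_chrom = 1, length_bp = 2e4, n_sites = 10,
                               seed = 1),
               "infeasible packing")
  expect_error(simulate_genome(n_chrom = 1, length_bp = 1e4, n_sites = 2,
                               seed = 1),
               "infeasible packing")  # passes the 4 kb/site bound, not flanks
})

test_that("sim_truth invariants hold and are enforced", {
  sim <- small_sim(seed = 3)
  expect_silent(validate_sim_truth(sim$truth))
  s <- sim$truth$sites
  expect_true(all(s$start0 >= 2000 &
                    s$start0 + 8 <= sim$truth$chrom_lengths[s$chrom] - 2000))
  expect_true(all(diff(sort(s$start0)) >= 8))
  expect_true(all(s$cut_fraction[!s$cut] == 0))
  bad <- sim$truth
  bad$sites$cut_fraction[which(!bad$sites$cut)[1]] <- 0.5
  expect_error(validate_sim_truth(bad), "invariant")
})

test_that("emitted pairs use only proper FLAG combinations 99/147 and 83/163", {
  sim <- small_sim(seed = 4, n_sites = 10, n_cut = 5, length_bp = 1e5)
  reads <- simulate_mnet(sim$genome, sim$truth, sim$genes, induced = TRUE,
                         seed = 1)
  first <- reads[bitwAnd(flag, 0x40L) != 0L]
  second <- reads[bitwAnd(flag, 0x80L) != 0L]
  expect_setequal(unique(first$flag), c(99L, 83L))
  expect_setequal(unique(second$flag), c(147L, 163L))
  fp <- merge(first[, .(qname, f1 = flag)], second[, .(qname, f2 = flag)],
              by = "qname")
  expect_true(all((fp$f1 == 99 & fp$f2 == 147) |
                    (fp$f1 == 83 & fp$f2 == 163)))
  ## mate fields are mutually consistent
  m <- merge(first[, .(qname, pos, pnext)],
             second[, .(qname, pos2 = pos, pnext2 = pnext)], by = "qname")
  expect_identical(m$pnext, m$pos2)
  expect_identical(m$pnext2, m$pos)
})

test_that("uninduced alignments show no site-proximal excess", {
  sim <- small_sim(seed = 8, background_rate = 10)
  reads <- simulate_mnet(sim$genome, sim$truth, sim$genes, induced = FALSE,
                         seed = 2)
  path <- sam_tempfile(reads, sim$truth$chrom_lengths)
  prof <- build_profile(path)
  cnt <- prof$counts
  ## per gene: signal within +/-500 bp of its site vs uniform expectation
  s <- sim$truth$sites
  genes <- as.data.frame(sim$genes)
  obs <- exp_prop <- numeric(nrow(s))
  tot <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    g <- genes[genes$gene_id == s$gene_id[i], ]
    ing <- cnt[pos >= g$start & pos <= g$end, ]
    tot[i] <- sum(ing$count)
    obs[i] <- sum(ing[abs(pos - (s$start0[i] + 1)) <= 500, count])
    win <- min(s$start0[i] + 1 + 500, g$end) - max(s$start0[i] + 1 - 500,
                                                   g$start) + 1
    exp_prop[i] <- win / (g$end - g$start + 1)
  }
  pval <- stats::chisq.test(c(sum(obs), sum(tot) - sum(obs)),
                            p = c(mean(exp_prop), 1 - mean(exp_prop)))$p.value
  expect_gt(pval, 0.01)
})

test_that("induced cut sites emit reads on both strands near the site", {
  hit <- vapply(1:30, function(sd) {
    sim <- simulate_genome(n_chrom = 1, length_bp = 1e4, n_sites = 1,
                           n_cut = 1, cut_fraction = 0.9,
                           induction_rate = 500, background_rate = 0,
                           seed = sd)
    reads <- simulate_mnet(sim$genome, sim$truth, sim$genes, induced = TRUE,
                           seed = sd + 500)
    prof <- build_profile(sam_tempfile(reads, sim$truth$chrom_lengths))
    near <- prof$counts[abs(pos - (sim$truth$sites$start0 + 1)) <= 250]
    all(c("+", "-") %in% near$strand)
  }, logical(1))
  expect_true(all(hit))
})

test_that("ChIP treatment/control ratio converges to the enrichment at cut sites", {
  sim <- small_sim(seed = 6, n_sites = 10, n_cut = 5, length_bp = 1e5)
  chip <- simulate_chip(sim$truth, depth = 2000, seed = 9)
  s <- sim$truth$sites
  ratio_in_window <- function(i) {
    mid <- s$start0[i] + 4.5
    tw <- chip$treatment[abs((GenomicRanges::start(chip$treatment) +
                                GenomicRanges::end(chip$treatment)) / 2 -
                               mid) <= 2000]
    cw <- chip$control[abs((GenomicRanges::start(chip$control) +
                              GenomicRanges::end(chip$control)) / 2 -
                             mid) <= 2000]
    mean(tw$score) / mean(cw$score)
  }
  cut_r <- vapply(which(s$cut), ratio_in_window, 0)
  uncut_r <- vapply(which(!s$cut), ratio_in_window, 0)
  expect_true(all(abs(cut_r - 8) < 0.5))
  expect_true(all(abs(uncut_r - 1) < 0.1))
  ## enrichment 1: expected treatment equals expected control everywhere
  sim1 <- small_sim(seed = 6, n_sites = 10, n_cut = 5, length_bp = 1e5,
                    chip_enrichment = 1)
  chip1 <- simulate_chip(sim1$truth, depth = 2000, seed = 9)
  expect_lt(abs(mean(chip1$treatment$score) / mean(chip1$control$score) - 1),
            0.01)
})

test_that("Ct shifts equal -log2(1-f) and f=1 is rejected", {
  sim <- simulate_genome(n_chrom = 1, length_bp = 2e4, n_sites = 3, n_cut = 3,
                         cut_fraction = c(0.5, 0.75, 0), ct_noise_sd = 0,
                         seed = 2)
  ctab <- simulate_ct(sim$truth, replicates = 1, seed = 1)
  sh <- function(amp) {
    ctab$ct[ctab$amplicon_id == amp & ctab$condition == "treated"] -
      ctab$ct[ctab$amplicon_id == amp & ctab$condition == "untreated"]
  }
  s <- sim$truth$sites
  expect_equal(sh(paste0("acDS_", s$site_id[s$cut_fraction == 0.5])), 1.0)
  expect_equal(sh(paste0("acDS_", s$site_id[s$cut_fraction == 0.75])), 2.0)
  expect_equal(sh("noDSB"), 0)
  expect_equal(sh("ACTB"), 0)
  ## baselines drawn in [18, 26]
  base <- ctab$ct[ctab$condition == "untreated"]
  expect_true(all(base >= 18 & base <= 26))
  simbad <- sim
  simbad$truth$sites$cut_fraction[1] <- 1
  expect_error(simulate_ct(simbad$truth, seed = 1),
               "infinite|cut_fraction")
})
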