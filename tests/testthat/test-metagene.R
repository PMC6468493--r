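test_that("site_matrix places counts at gene-oriented offsets", {
  ## + strand host gene, site 0-based start 100: count at (pos0 110, '+')
  ## lands at sense offset +10
  prof <- manual_profile("chr1", "+", pos = 111L)  # 1-based
  m <- site_matrix(prof, one_site(100, "+"), flank = 50)
  expect_equal(unname(m$sense[1, which(m$offsets == 10)]), 1)
  expect_equal(sum(m$sense), 1)
  expect_equal(sum(m$antisense), 0)
  ## - strand host gene, site [100,108): count at (pos0 97, '-') is sense +10
  prof2 <- manual_profile("chr1", "-", pos = 98L)
  m2 <- site_matrix(prof2, one_site(100, "-"), flank = 50)
  expect_equal(unname(m2$sense[1, which(m2$offsets == 10)]), 1)
  expect_equal(sum(m2$antisense), 0)
  ## same position on '+' is antisense in the flipped frame
  m3 <- site_matrix(manual_profile("chr1", "+", 98L), one_site(100, "-"),
                    flank = 50)
  expect_equal(unname(m3$antisense[1, which(m3$offsets == 10)]), 1)
})

test_that("sites outside chromosome bounds are dropped, not zero-padded", {
  prof <- manual_profile("chr1", "+", 500L)
  near_edge <- one_site(100, "+", seqlen = 50000L)
  expect_message(m <- site_matrix(prof, c(near_edge, one_site(10000, "+",
                                                              seqlen = 50000L)),
                                  flank = 2000),
                 "dropped")
  expect_equal(nrow(m$sense), 1L)
  expect_error(site_matrix(prof, near_edge, flank = 2000), "no site window")
  expect_error(site_matrix(prof, GenomicRanges::GRanges()), "empty")
})

test_that("matrix column sums match an independent windowed count", {
  sim <- small_sim(seed = 61, n_sites = 8, n_cut = 4, length_bp = 8e4)
  path <- sam_tempfile(simulate_mnet(sim$genome, sim$truth, sim$genes,
                                     induced = TRUE, seed = 62),
                       sim$truth$chrom_lengths)
  prof <- build_profile(path)
  ann <- annotate_sites(scan_sites(sim$genome), sim$genes)
  flank <- 300L
  m <- site_matrix(prof, ann, flank = flank)
  cnt <- as.data.frame(prof$counts)
  for (i in seq_along(ann)) {
    gs <- ann$gene_strand[i]
    anchor <- if (gs == "+") GenomicRanges::start(ann)[i] else
      GenomicRanges::end(ann)[i]
    w <- cnt[cnt$pos >= anchor - flank & cnt$pos <= anchor + flank, ]
    expect_equal(sum(m$sense[i, ]), sum(w$count[w$strand == gs]))
    expect_equal(sum(m$antisense[i, ]), sum(w$count[w$strand != gs]))
    ## spot-check one offset column against direct lookup
    off <- 25L
    p <- if (gs == "+") anchor + off else anchor - off
    expect_equal(unname(m$sense[i, which(m$offsets == off)]),
                 sum(w$count[w$strand == gs & w$pos == p]))
  }
})

test_that("average_profile is the column mean and is linear", {
  sim_mat <- function(vals) {
    structure(list(offsets = -2:2, sense = vals, antisense = vals * 0,
                   site_ids = rownames(vals), flank = 2L),
              class = "metagene_matrix")
  }
  two <- sim_mat(rbind(a = c(0, 0, 2, 0, 0), b = c(0, 0, 0, 0, 0)))
  pr <- average_profile(two)
  expect_equal(pr$mean_sense, c(0, 0, 1, 0, 0))
  expect_equal(pr$n_sites, 2L)
  one <- sim_mat(rbind(a = c(1, 2, 3, 4, 5)))
  expect_equal(average_profile(one)$mean_sense, c(1, 2, 3, 4, 5))
  set.seed(9)
  A <- sim_mat(matrix(rpois(20, 3), 4, 5,
                      dimnames = list(paste0("s", 1:4), NULL)))
  B <- sim_mat(matrix(rpois(10, 3), 2, 5,
                      dimnames = list(paste0("t", 1:2), NULL)))
  AB <- sim_mat(rbind(A$sense, B$sense))
  expect_equal(average_profile(AB)$mean_sense,
               (4 * average_profile(A)$mean_sense +
                  2 * average_profile(B)$mean_sense) / 6)
})

test_that("rolling_smooth matches the forward-window definition", {
  expect_equal(rolling_smooth(c(0, 0, 5, 0, 0, 0, 0), window = 5),
               c(1, 1, 1, 0, 0, 0, 0))
  ## constants unchanged; right edge shrinks to the available positions
  expect_equal(rolling_smooth(rep(3.5, 10), window = 5), rep(3.5, 10))
  x <- c(4, 0, 0, 0, 0, 0, 8)
  sm <- rolling_smooth(x, window = 5)
  expect_equal(sm[7], 8)                      # last position: window of 1
  expect_equal(sm[5], mean(x[5:7]))           # shrinking window
  expect_lte(max(rolling_smooth(x, 5)), max(x))
  ## profile objects smooth both orientations and flag it
  prof <- structure(list(offsets = 0:6,
                         mean_sense = c(0, 0, 5, 0, 0, 0, 0),
                         mean_antisense = rep(2, 7), smoothed = FALSE,
                         n_sites = 1L), class = "metagene_profile")
  sm2 <- rolling_smooth(prof)
  expect_true(sm2$smoothed)
  expect_equal(sm2$mean_sense, c(1, 1, 1, 0, 0, 0, 0))
  expect_equal(sm2$mean_antisense, rep(2, 7))
})

test_that("proximal/distal ratio follows its definition", {
  mk <- function(sense, antisense, flank) {
    structure(list(offsets = -flank:flank, sense = sense,
                   antisense = antisense,
                   site_ids = rownames(sense), flank = flank),
              class = "metagene_matrix")
  }
  F <- 2000L
  unit <- matrix(1, 1, 2 * F + 1, dimnames = list("u", NULL))
  m <- mk(unit, unit, F)
  st <- proximal_distal_stat(m, pseudocount = 1e-9)
  expect_equal(st$per_site$ratio, 1, tolerance = 1e-9)
  ## proximal sum 10, distal 0, pseudocount 1 -> ratio 11
  z <- matrix(0, 1, 2 * F + 1, dimnames = list("z", NULL))
  z[1, F + 1 + 100] <- 10  # offset +100, sense only
  st2 <- proximal_distal_stat(mk(z, z * 0, F))
  expect_equal(st2$per_site$proximal, 10)
  expect_equal(st2$per_site$distal, 0)
  expect_equal(st2$per_site$ratio, 11)
  ## symmetric mode counts the mirrored upstream windows too
  z2 <- z
  z2[1, F + 1 - 100] <- 7  # offset -100
  st3 <- proximal_distal_stat(mk(z2, z2 * 0, F), symmetric = TRUE)
  expect_equal(st3$per_site$proximal, 17)
  ## summary quartiles across sites
  sm <- mk(rbind(a = z[1, ], b = 2 * z[1, ], c = 3 * z[1, ]),
           matrix(0, 3, 2 * F + 1), F)
  su <- proximal_distal_stat(sm)$summary
  expect_equal(su$median, 21)
  expect_equal(su$n_sites, 3)
})

test_that("induced cut sites show higher proximal/distal ratios than uncut", {
  sim <- small_sim(seed = 71)
  path <- sam_tempfile(simulate_mnet(sim$genome, sim$truth, sim$genes,
                                     induced = TRUE, seed = 72),
                       sim$truth$chrom_lengths)
  prof <- build_profile(path)
  ann <- annotate_sites(scan_sites(sim$genome), sim$genes)
  truth <- sim$truth$sites
  cut_m <- site_matrix(prof, ann[match(truth$site_id[truth$cut],
                                       ann$site_id)])
  uncut_m <- site_matrix(prof, ann[match(truth$site_id[!truth$cut],
                                         ann$site_id)])
  st_cut <- proximal_distal_stat(cut_m)
  st_uncut <- proximal_distal_stat(uncut_m)
  expect_gt(st_cut$summary$median, st_uncut$summary$median)
})

test_that("gene-oriented frames are invariant under genome reversal", {
  ## a '+' gene site with signal downstream equals the mirrored '-' gene
  ## site with mirrored signal
  prof_fwd <- manual_profile(rep("chr1", 3), c("+", "+", "-"),
                             c(1111, 1150, 1090))
  m_fwd <- site_matrix(prof_fwd, one_site(1100, "+"), flank = 100)
  L <- 10000L
  mirror <- function(p) L - p + 1L
  prof_rev <- manual_profile(rep("chr1", 3), c("-", "-", "+"),
                             mirror(c(1111, 1150, 1090)))
  m_rev <- site_matrix(prof_rev, one_site(L - 1100 - 8L, "-"), flank = 100)
  expect_equal(m_fwd$sense[1, ], m_rev$sense[1, ])
  expect_equal(m_fwd$antisense[1, ], m_rev$antisense[1, ])
})
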