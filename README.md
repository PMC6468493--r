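# dsbtx

Nascent RNA polymerase II (RNAPII) transcription at sequence-specific DNA
double-strand breaks (DSBs), as an end-to-end, tested R pipeline.

In the DIvA system, an AsiSI–estrogen-receptor fusion endonuclease is driven
into the nucleus with 4-hydroxytamoxifen and cleaves its palindromic 8-bp
recognition sequence `GCGATCGC` at a fixed set of genomic loci, creating
reproducible, sequence-specific DSBs. `dsbtx` implements the computational
side of studying transcription at these breaks, for genomicists who have
mNET-seq alignments, damage-mark ChIP tracks and qPCR Ct tables in hand:

* **Site discovery** — scan a genome for `GCGATCGC` (its own reverse
  complement, so one forward scan enumerates every cleavable locus exactly
  once) and annotate each site as genic/intergenic with the host-gene
  strand (`scan_sites()`, `annotate_sites()`).
* **Single-nucleotide RNAPII profiles** — from properly paired mNET-seq
  alignments (FLAG combinations 99/147 and 83/163 only), the signal is the
  reference coordinate of the 3′-most aligned base of read 2 on the strand
  of read 1, CIGAR-aware; this base marks the polymerase position
  (`accept_pair()`, `pair_signal()`, `build_profile()`).
* **Cut/uncut classification** — per site, the damage score is
  `log2((T + p)/(C + p))` with `T`, `C` the mean per-bp CPM of the γH2A.X
  and H2A.X tracks over the site ±1 kb; the top-*n* sites are "cut", the
  bottom-*n* the "uncut" negative controls (`score_sites()`,
  `select_cut_uncut()`).
* **Metagene statistics** — gene-oriented sense/antisense matrices around
  site 5′ ends (offset 0 = site 5′ end), per-offset averages, a forward
  5-nt rolling mean (`smoothed[x] = mean(raw[x..x+4])`), and a per-site
  proximal/distal ratio `(Σ signal[0,500) + 1)/(Σ signal[1500,2000) + 1)`
  summarized by median and quartiles (`site_matrix()`, `average_profile()`,
  `rolling_smooth()`, `proximal_distal_stat()`).
* **%DSB from qPCR** — double-normalized ΔΔCt: Ct against the housekeeping
  mean within condition, then against the untreated condition;
  `fold = 2^(−ΔΔCt)`, `%DSB = (1 − fold) × 100` (`quantify_dsb()`).
* **Synthetic data with ground truth** — a generator for toy genomes with
  planted sites, paired-end SAM alignments, ChIP bedGraph tracks and Ct
  tables (`simulate_genome()`, `simulate_mnet()`, `simulate_chip()`,
  `simulate_ct()`, `simulate_dataset()`), so every stage is testable
  offline.

`run_pipeline()` chains the stages on files (FASTA, BED6, SAM/BAM,
bedGraph, CSV) and writes per-stage outputs plus a JSON manifest with input
checksums; reruns are byte-identical. A thin command-line dispatcher ships
in `inst/scripts/dsbtx`.

## Worked example

```r
library(dsbtx)

dir <- "demo_run"
paths <- simulate_dataset(dir, seed = 81, n_sites = 12, n_cut = 4,
                          length_bp = 1.2e5)
manifest <- run_pipeline(list(
  genome = paths$genome, annotation = paths$genes,
  alignments = paths$alignments,
  chip_treatment = paths$chip_treatment,
  chip_control = paths$chip_control,
  ct_table = paths$ct_table,
  outdir = file.path(dir, "out"), n_cut = 4, seed = 81))

manifest$stages
#> [1] "scan" "annotate" "profile" "classify" "metagene" "stats" "dsb_qpcr"

read.delim(file.path(dir, "out", "prox_distal_summary.tsv"))
#>   site_set n_sites       q1 median     q3
#> 1      cut       4 126.9583 209.75 283.25
#> 2    uncut       4   0.8750   1.50   2.00
```

The cut-site median proximal/distal ratio (209.75) dwarfs the uncut median
(1.50): break-proximal nascent transcription is concentrated within ~500 bp
of cleaved sites, while uncut sites show only background. The %DSB
estimates recover the planted per-site cut fraction (0.8) from the Ct
tables up to Ct noise:

```r
est <- read.csv(file.path(dir, "out", "dsb_estimates.csv"))
subset(est, condition == "treated",
       c(amplicon_id, role, fold_change, percent_dsb))
#>    amplicon_id          role fold_change percent_dsb
#> 1         ACTB  housekeeping       1.064       -6.42
#> 2        GAPDH  housekeeping       0.947        5.29
#> 3 acDS_site001        target       0.166       83.40
#> 4 acDS_site009        target       0.179       82.13
#> 5 acDS_site010        target       0.168       83.24
#> 6 acDS_site011        target       0.161       83.86
#> 7        noDSB control_locus       0.926        7.36
```

Target amplicons report ~80% broken alleles; housekeeping and the
non-restricted control locus scatter around 0% within qPCR noise
(σ = 0.1 cycles here). See the methods vignette
(`vignettes/dsbtx-methods.Rmd`) for the models, parameter defaults and
design decisions.

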