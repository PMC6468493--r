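---
title: "Profiling nascent RNAPII transcription at sequence-specific DNA double-strand breaks"
author: "dsbtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling nascent RNAPII transcription at sequence-specific DNA double-strand breaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbtx)
```

## The analysis

`dsbtx` implements a complete desk-side pipeline for studying nascent RNA
polymerase II (RNAPII) transcription at sequence-specific DNA double-strand
breaks (DSBs) created by the AsiSI restriction endonuclease. In the widely
used DIvA system, an AsiSI–estrogen-receptor fusion is driven into the
nucleus with 4-hydroxytamoxifen and cleaves its 8-bp recognition sequence
`GCGATCGC` at a defined set of genomic loci, so the same break positions
recur in every cell. The pipeline answers, stage by stage:

1. *Where can the enzyme cut?* — a motif scan of the genome plus genic
   annotation (`scan_sites()`, `annotate_sites()`).
2. *Where did it actually cut?* — a γH2A.X/H2A.X ChIP log2 ratio per site,
   ranked to select "cut" and "uncut" site sets (`score_sites()`,
   `select_cut_uncut()`).
3. *Where is RNAPII, base by base?* — strand-specific single-nucleotide
   3′-end profiles from paired-end mNET-seq alignments (`build_profile()`).
4. *What does transcription look like around breaks?* — gene-oriented
   sense/antisense metagene profiles, a 5-nt rolling average, and a
   proximal/distal signal ratio per site (`site_matrix()`,
   `average_profile()`, `rolling_smooth()`, `proximal_distal_stat()`).
5. *How efficiently was each locus cleaved?* — %DSB from qPCR Ct tables via
   the double-normalized ΔΔCt method (`quantify_dsb()`).

Every stage is exercised against a synthetic-data generator with known
ground truth, so the whole pipeline is testable without sequencing data.

## Models and conventions

### Site discovery

`GCGATCGC` is palindromic (it equals its own reverse complement), so a
single forward-strand scan enumerates each cleavable position exactly once;
scanning both strands would double-count every locus. Matching is exact and
windows containing `N` never match. Matching is delegated to
`Biostrings::matchPattern()`; the test suite verifies it against an
exhaustive 8-mer window oracle written independently of `Biostrings`. A
site is *genic* when its 8-bp interval overlaps a gene body by at least
1 bp. Overlaps with several genes are resolved by the larger overlap, then
alphabetically by gene id (deterministic and logged). Because "genic" is
annotation-dependent, the package reports counts per supplied annotation
and hard-codes no census. Promoter-proximal sites can be captured with
`promoter_extension`, which extends genes upstream (default 0 bp).

Coordinates are 1-based inclusive inside R (the GRanges/SAM convention);
all BED and bedGraph output is 0-based half-open.

### The single-nucleotide RNAPII signal

mNET-seq reads are sequenced from RNA protected by immunoprecipitated
RNAPII; the 3′-most nucleotide of the nascent RNA marks the polymerase
position. For a properly paired library this maps to the alignment rule:
take the reference coordinate of the 3′-most aligned base of read 2 (its
rightmost base when read 2 is forward, leftmost when reverse) and the
strand of read 1. Only FLAG combinations 99/147 and 83/163 are accepted —
proper, primary, FR pairs — and everything else (non-proper, secondary,
supplementary, singletons) is rejected. The aligned span is CIGAR-aware, so
soft clips never shift the 3′ end. No deduplication and no MAPQ threshold
are applied by default; `min_mapq` and `flip_strand` exist because library
chemistries differ in orientation convention, but the literal
strand-of-read-1 rule is the default.

### Cut/uncut classification

Damage is scored per site as `log2((T + p)/(C + p))`, with `T` and `C` the
mean per-bp CPM of the γH2A.X (treatment) and H2A.X (control) tracks over
the site ±1 kb. CPM normalization (`sum(score × width) = 10^6`) removes
library size; the pseudocount `p = 1` CPM (the convention of standard
ChIP-ratio tools) stabilizes sparse windows. Neither the window nor the
pseudocount of the original ratio computation is published, so both are
exposed as parameters (`window_bp`, `pseudocount`) and the defaults are
documented assumptions. Sites are ranked once by decreasing score with ties
broken by genomic coordinate; the top `n` are labelled cut and the bottom
`n` uncut (the reference analysis uses `n = 94` on hg38; the synthetic
pipeline uses small `n`).

### Metagene frame

Offset 0 is the 5′ end of the 8-bp site *in the orientation of the host
gene*: for a `+` gene, `offset = pos − site_start` and sense = `+` strand;
for a `−` gene the axis and strand labels flip. This lets sites hosted on
either strand average coherently; a `reference` orientation mode exists for
intergenic sites. Sites whose ±flank window (default 2 kb) would leave the
chromosome are dropped rather than zero-padded, which avoids edge bias in
the mean. Matrices hold raw counts; scaling to equal accepted-pair totals
is applied only when two libraries are compared.

The 5-nt rolling average is forward-looking — position `x` becomes the mean
over `[x, x+4]` — with a shrinking window at the right edge, so the last
position is unchanged and constants are invariant.

The per-site break-transcription statistic divides the combined
sense+antisense signal in a proximal window (offsets `[0, 500)`) by a
distal window (`[1500, 2000)`), `ratio = (proximal + 1)/(distal + 1)`.
Whether the proximal window of the original box-plot statistic is one- or
two-sided is not stated; the one-sided downstream choice is the default
here and a `symmetric` flag mirrors both windows. Medians and quartiles are
reported across sites, per condition.

### ΔΔCt quantitation of %DSB

Cleaved templates are not amplified, so an amplicon spanning a site with
cut fraction `f` loses a fraction `f` of its template and its Ct rises by
`−log2(1 − f)` cycles. The estimator is the classic double normalization:
`ΔCt` against the housekeeping mean within each condition and replicate,
`ΔΔCt` against the untreated condition paired by replicate index,
`fold = 2^(−ΔΔCt)` (untreated ≡ 1), and `%DSB = (1 − fold) × 100`,
reported unclamped so signal gain shows as negative values. With zero Ct
noise this recovers `100·f` exactly — an algebraic identity the tests
assert. With two housekeeping genes the instruction "either of the two" is
ambiguous; the default uses the mean of both (a constant offset between
housekeeping genes cancels in ΔΔCt) and per-housekeeping estimates are
attached for transparency. Drug-preincubation conditions are normalized
against the same untreated baseline as plain induction.

## The synthetic-data generator

The generator emulates the statistical structure of the study — not the
sequences of any real genome — and its defaults are the study conditions
under which all acceptance properties are tested:

* **Genome and sites.** Uniform A/C/G/T chromosomes with the motif planted
  in disjoint 4-kb slots, ≥ 2 kb from chromosome ends (full metagene
  windows always fit). Spontaneous motif occurrences are destroyed by
  single-base substitution and the sequence re-scanned until the planted
  set is exactly the occurring set, so the site census is truth-exact.
  In-slot jitter is bounded so consecutive sites stay at least
  `chip_spread + 1200` bp apart: the ChIP enrichment domain of one site
  never reaches into the damage-score window of its neighbour. One gene of
  3–5 kb surrounds each genic site, with uniformly random strand.
* **Reads.** Fixed insert 150 bp, read length 50 bp, ungapped `50M`
  alignments, FLAGs 99/147 or 83/163, no duplicates and no quality model —
  the profiled statistic depends only on the 3′-end position and strand.
  Background transcription is Poisson per gene (default 2 pairs/kb),
  uniform over the gene body on the gene strand. Induction adds, per cut
  site and per strand, Poisson(`induction_rate × cut_fraction`) pairs
  (default rate 200) whose downstream offset is geometric with mean
  `decay_length = 250` bp truncated at 2 kb, matching a break-proximal
  signal extent of roughly a kilobase. Both strands receive this
  break-proximal signal (bidirectional transcription at breaks).
* **ChIP.** Binned Poisson tracks (50-bp bins): control flat at `depth`,
  treatment adding a boxcar of half-width `chip_spread = 2000` bp and
  amplitude `(chip_enrichment − 1) × depth` (default enrichment 8) around
  cut sites only.
* **Ct tables.** Per-amplicon baselines uniform in [18, 26] cycles, Gaussian
  cycle noise (default σ = 0.1), treated shift `−log2(1 − f)`. A cut
  fraction of 1 is rejected (infinite shift). Default cut fraction 0.8 on
  half the sites.

What the generator does *not* model — sequencing errors, fragment-length
variation, PCR duplicates, splicing, mappability, replication timing,
chromatin context — bounds what the passing tests show: they demonstrate
that the implementation computes its statistics correctly and recovers
planted parameters under the stated generative model, not that the
biological conclusions hold on any particular real dataset.

## Problem sizes and determinism

The test and acceptance runs use deliberately small instances chosen so the
statistical checks are sharp: a 1-Mb chromosome for the scanner oracle,
about 11,000 read pairs for the 3′-end oracle, 40 sites (20 cut) per seed
for classification over 20 seeds, 20 sites per seed over several seeds for
the metagene direction check, and 200 Monte-Carlo trials for the noisy
%DSB recovery. At ChIP depth 50 per bin and enrichment 8 the cut/uncut
score separation is ~2.3 log2 units against a Poisson noise SD well under
0.1, so perfect label recovery is the expected behaviour, not a lucky
draw. All randomness flows through explicit integer seeds; identical seeds
give byte-identical genomes, truth tables, SAM records, tracks and Ct
tables, and `run_pipeline()` reruns are byte-identical per file.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile("demo")
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
read.delim(file.path(dir, "out", "prox_distal_summary.tsv"))
```

## Known limitations

* The generator's read model is intentionally rigid (fixed insert, no
  indels); CIGAR handling beyond `50M` is covered by unit tests, not by the
  simulator.
* `select_cut_uncut()` assumes one score per site; replicate-aware
  differential-binding selection is out of scope.
* The proximal/distal statistic is descriptive (median and quartiles);
  no between-condition test statistic is computed.
* Amplification-efficiency calibration of qPCR (standard curves) is not
  modelled; ΔΔCt assumes doubling per cycle.
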