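#' Write a complete simulated dataset to disk
#'
#' Runs the whole synthetic-data module and writes every input the analysis
#' pipeline consumes: genome FASTA, gene BED6, paired-end SAM (induced and,
#' optionally, uninduced), treatment/control bedGraph ChIP tracks, Ct CSV
#' and a JSON ground-truth sidecar.
#'
#' @param dir output directory (created).
#' @param seed master seed; stage seeds are derived deterministically.
#' @param chip_depth control ChIP counts per bin.
#' @param uninduced also write an uninduced alignment file.
#' @param ... passed to [simulate_genome()].
#' @return named list of file paths plus the `truth` object, invisibly.
#' @export
simulate_dataset <- function(dir, seed = 1L, chip_depth = 50,
                             uninduced = FALSE, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(seed = seed, ...)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.bed"),
    alignments = file.path(dir, "reads_induced.sam"),
    chip_treatment = file.path(dir, "chip_treatment.bedgraph"),
    chip_control = file.path(dir, "chip_control.bedgraph"),
    ct_table = file.path(dir, "ct.csv"),
    truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  sim$genes$name <- sim$genes$gene_id
  write_bed6(sim$genes, paths$genes)
  reads <- simulate_mnet(sim$genome, sim$truth, sim$genes, induced = TRUE,
                         seed = seed + 101L)
  write_sam(reads, sim$truth$chrom_lengths, paths$alignments)
  if (uninduced) {
    paths$alignments_uninduced <- file.path(dir, "reads_uninduced.sam")
    reads0 <- simulate_mnet(sim$genome, sim$truth, sim$genes,
                            induced = FALSE, seed = seed + 202L)
    write_sam(reads0, sim$truth$chrom_lengths, paths$alignments_uninduced)
  }
  chip <- simulate_chip(sim$truth, depth = chip_depth, seed = seed + 303L)
  write_bedgraph(chip$treatment, paths$chip_treatment, keep_zero = TRUE)
  write_bedgraph(chip$control, paths$chip_control, keep_zero = TRUE)
  write_ct_table(simulate_ct(sim$truth, seed = seed + 404L), paths$ct_table)
  write_sim_truth(sim$truth, paths$truth)
  invisible(c(paths, list(truth = sim$truth)))
}

#' Run the full DSB-transcription analysis pipeline
#'
#' Chains the analysis stages on files on disk: site scan -> genic
#' annotation -> 3'-end profile -> cut/uncut classification -> metagene
#' matrices and averaged/smoothed profiles -> proximal/distal statistic
#' (-> %DSB quantitation when a Ct table is supplied). Per-stage outputs
#' and a JSON manifest (input checksums, effective parameters, stage list)
#' are written to `config$outdir`; a rerun with identical inputs and config
#' reproduces byte-identical outputs.
#'
#' @param config a named list or a YAML file path. Required fields:
#'   `genome`, `annotation`, `alignments`, `chip_treatment`,
#'   `chip_control`, `outdir`. Optional: `ct_table`, `n_cut` (default 94),
#'   `flank` (2000), `window_bp` (1000), `pseudocount` (1), `proximal`
#'   (`c(0, 500)`), `distal` (`c(1500, 2000)`), `promoter_extension` (0),
#'   `min_mapq` (0), `flip_strand` (FALSE), `seed` (1).
#' @return the run manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("genome", "annotation", "alignments", "chip_treatment",
                "chip_control", "outdir")
  for (f in required)
    if (is.null(config[[f]]))
      stop("config field missing: ", f)
  p <- list(
    n_cut = as.integer(config$n_cut %||% 94L),
    flank = as.integer(config$flank %||% 2000L),
    window_bp = as.integer(config$window_bp %||% 1000L),
    pseudocount = as.numeric(config$pseudocount %||% 1.0),
    proximal = as.integer(config$proximal %||% c(0L, 500L)),
    distal = as.integer(config$distal %||% c(1500L, 2000L)),
    promoter_extension = as.integer(config$promoter_extension %||% 0L),
    min_mapq = as.integer(config$min_mapq %||% 0L),
    flip_strand = isTRUE(config$flip_strand),
    seed = as.integer(config$seed %||% 1L))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  inputs <- config[intersect(names(config),
                             c(required[-6], "ct_table"))]
  for (f in names(inputs))
    if (!file.exists(inputs[[f]]))
      stop("stage setup failed: input file for '", f, "' not found: ",
           inputs[[f]])
  manifest <- list(package = "dsbtx", stages = character(0),
                   inputs = lapply(inputs, function(x)
                     list(path = x, md5 = unname(tools::md5sum(x)))),
                   parameters = p)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages <<- c(manifest$stages, name)
    message("[dsbtx] stage ", name, " done")
    res
  }

  sites <- stage("scan", scan_sites(config$genome))
  sites <- stage("annotate", {
    genes <- read_genes_bed(config$annotation)
    s <- annotate_sites(sites, genes,
                        promoter_extension = p$promoter_extension)
    write_sites_bed(s, file.path(outdir, "sites.bed"))
    s
  })
  profile <- stage("profile", {
    pr <- build_profile(config$alignments, min_mapq = p$min_mapq,
                        flip_strand = p$flip_strand)
    export_bedgraph(pr, "+", file.path(outdir, "profile_plus.bedgraph"))
    export_bedgraph(pr, "-", file.path(outdir, "profile_minus.bedgraph"),
                    negate = TRUE)
    pr
  })
  labels <- stage("classify", {
    scores <- score_sites(sites, read_bedgraph(config$chip_treatment),
                          read_bedgraph(config$chip_control),
                          window_bp = p$window_bp,
                          pseudocount = p$pseudocount)
    lab <- select_cut_uncut(scores, n = p$n_cut, genic_only = TRUE)
    data.table::fwrite(lab$scores, file.path(outdir, "site_scores.tsv"),
                       sep = "\t")
    lab
  })
  mats <- stage("metagene", {
    mk <- function(ids) {
      sel <- sites[match(ids, sites$site_id)]
      site_matrix(profile, sel, flank = p$flank)
    }
    m <- list(cut = mk(labels$cut), uncut = mk(labels$uncut))
    for (nm in names(m)) {
      prof <- rolling_smooth(average_profile(m[[nm]]), window = 5L)
      write_metagene_tsv(prof, file.path(
        outdir, paste0("metagene_", nm, "_smoothed.tsv")))
    }
    m
  })
  stats <- stage("stats", {
    st <- lapply(mats, proximal_distal_stat, proximal = p$proximal,
                 distal = p$distal, pseudocount = p$pseudocount)
    summ <- data.table::rbindlist(
      lapply(st, `[[`, "summary"), idcol = "site_set")
    data.table::fwrite(summ, file.path(outdir, "prox_distal_summary.tsv"),
                       sep = "\t")
    per <- data.table::rbindlist(
      lapply(st, `[[`, "per_site"), idcol = "site_set")
    data.table::fwrite(per, file.path(outdir, "prox_distal_per_site.tsv"),
                       sep = "\t")
    st
  })
  if (!is.null(config$ct_table)) {
    stage("dsb_qpcr", {
      est <- quantify_dsb(config$ct_table)
      write.csv(est, file.path(outdir, "dsb_estimates.csv"),
                row.names = FALSE, quote = FALSE)
      est
    })
  }
  outputs <- list.files(outdir, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(outdir, "manifest.json"))
  manifest$outputs <- lapply(outputs, function(x)
    list(path = basename(x), md5 = unname(tools::md5sum(x))))
  manifest$n_sites <- length(sites)
  manifest$n_genic <- sum(sites$genic, na.rm = TRUE)
  manifest$n_pairs_accepted <- profile$n_pairs_accepted
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ## effective config alongside outputs, for reproducibility
  yaml::write_yaml(c(inputs, p), file.path(outdir, "config_used.yaml"))
  invisible(manifest)
}
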