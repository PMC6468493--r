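#' Simulate a qPCR Ct table for DSB quantitation
#'
#' Models the loss of intact (non-restricted) genomic template at cut sites:
#' an amplicon spanning a site with cut fraction `f` retains a fraction
#' `1 - f` of template after induction, so its treated Ct rises by
#' `-log2(1 - f)` cycles over its untreated baseline. Housekeeping and
#' uncut control-locus amplicons have `f = 0`. Per-amplicon baseline Ct
#' values are drawn once, uniformly in \[18, 26\]; every measurement gets
#' independent `Normal(0, ct_noise_sd)` cycle noise.
#'
#' @param truth `sim_truth` from [simulate_genome()].
#' @param amplicon_map data.frame with columns `amplicon_id`, `role`
#'   (`target`, `housekeeping` or `control_locus`) and `site_id` (`NA` for
#'   non-target roles); see [default_amplicon_map()].
#' @param replicates biological replicates per condition (>= 1).
#' @param seed integer seed.
#' @param conditions conditions to emit; must include `"untreated"`. All
#'   non-untreated conditions (e.g. `"treated"`, `"treated+drug"`) apply the
#'   cut-fraction Ct shift.
#' @return a `CtTable` data.frame: `amplicon_id, role, condition, replicate,
#'   ct`.
#' @export
simulate_ct <- function(truth, amplicon_map = default_amplicon_map(truth),
                        replicates = 3L, seed = 1L,
                        conditions = c("untreated", "treated")) {
  validate_sim_truth(truth)
  stopifnot(replicates >= 1, "untreated" %in% conditions)
  am <- data.table::as.data.table(amplicon_map)
  stopifnot(all(c("amplicon_id", "role", "site_id") %in% names(am)))
  bad <- setdiff(am$role, c("target", "housekeeping", "control_locus"))
  if (length(bad)) stop("unknown amplicon role(s): ", paste(bad, collapse = ", "))
  f <- rep(0, nrow(am))
  tgt <- am$role == "target"
  if (any(tgt)) {
    idx <- match(am$site_id[tgt], truth$sites$site_id)
    if (anyNA(idx)) stop("target amplicon maps to unknown site_id")
    f[tgt] <- truth$sites$cut_fraction[idx]
  }
  if (any(f >= 1))
    stop("cut fraction 1 gives an infinite Ct shift; cannot simulate")
  set.seed(seed)
  baseline <- runif(nrow(am), 18, 26)
  sdv <- truth$params$ct_noise_sd
  rows <- list()
  for (cond in conditions) {
    shift <- if (cond == "untreated") rep(0, nrow(am)) else -log2(1 - f)
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- data.table(
        amplicon_id = am$amplicon_id, role = am$role, condition = cond,
        replicate = r,
        ct = baseline + shift + rnorm(nrow(am), 0, sdv))
    }
  }
  out <- rbindlist(rows)
  setorder(out, condition, amplicon_id, replicate)
  as.data.frame(out)
}

#' Default amplicon panel for a simulated genome
#'
#' One target amplicon per planted site, one non-restricted control locus
#' (`noDSB`) and two housekeeping amplicons (`ACTB`, `GAPDH`), mirroring a
#' typical DSB-quantitation qPCR design.
#'
#' @param truth `sim_truth`.
#' @param sites site_ids to target (default: all cut sites, or all sites if
#'   none is cut).
#' @return amplicon map data.frame for [simulate_ct()].
#' @export
default_amplicon_map <- function(truth, sites = NULL) {
  s <- truth$sites
  if (is.null(sites))
    sites <- if (any(s$cut)) s$site_id[s$cut] else s$site_id
  rbind(
    data.frame(amplicon_id = paste0("acDS_", sites), role = "target",
               site_id = sites),
    data.frame(amplicon_id = "noDSB", role = "control_locus",
               site_id = NA_character_),
    data.frame(amplicon_id = c("ACTB", "GAPDH"), role = "housekeeping",
               site_id = NA_character_)
  )
}

#' Write / read a Ct table CSV
#'
#' @param ct_table CtTable data.frame.
#' @param path CSV path.
#' @return `path` invisibly (write); CtTable data.frame (read).
#' @export
write_ct_table <- function(ct_table, path) {
  write.csv(ct_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("amplicon_id", "role", "condition", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Ct table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}
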