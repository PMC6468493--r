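#' Housekeeping normalization of a Ct table (delta-Ct)
#'
#' First normalization step of the double-normalized ddCt procedure: each
#' measurement is expressed relative to the housekeeping signal of the same
#' condition and replicate,
#' `dCt(amplicon, condition, rep) = Ct(amplicon) - mean Ct(housekeeping)`.
#' With several housekeeping amplicons (the typical design uses two, e.g.
#' ACTB and GAPDH) the default reference is the mean of their Ct values;
#' passing `housekeeping_id` selects a single one. Housekeeping rows are
#' retained in the output (their dCt is relative to the same reference), so
#' the procedure can be audited per housekeeping gene.
#'
#' @param ct_table CtTable data.frame (`amplicon_id, role, condition,
#'   replicate, ct`).
#' @param housekeeping_id optional single housekeeping amplicon to use;
#'   default: mean over all `role == "housekeeping"` amplicons.
#' @return the table with a `dct` column added.
#' @export
delta_ct <- function(ct_table, housekeeping_id = NULL) {
  dt <- data.table::as.data.table(ct_table)
  need <- c("amplicon_id", "role", "condition", "replicate", "ct")
  stopifnot(all(need %in% names(dt)))
  hk_ids <- if (is.null(housekeeping_id))
    unique(dt[role == "housekeeping", amplicon_id]) else housekeeping_id
  if (length(hk_ids) == 0) stop("no housekeeping amplicon in Ct table")
  hk_tab <- dt[amplicon_id %in% hk_ids,
               .(hk = mean(ct)), by = .(condition, replicate)]
  missing <- setdiff(unique(dt$condition), unique(hk_tab$condition))
  if (length(missing))
    stop("housekeeping amplicon missing in condition(s): ",
         paste(missing, collapse = ", "))
  out <- hk_tab[dt, on = c("condition", "replicate")]
  if (anyNA(out$hk))
    stop("housekeeping measurement missing for some (condition, replicate)")
  out[, dct := ct - hk]
  out[, hk := NULL]
  as.data.frame(out[, .(amplicon_id, role, condition, replicate, ct, dct)])
}

#' Fold-change relative to the untreated condition (delta-delta-Ct)
#'
#' Second normalization step: per amplicon and replicate,
#' `ddCt = dCt(condition) - dCt(untreated)` (replicates paired by index),
#' and `fold = 2^(-ddCt)`. The untreated condition is thus exactly 1 in
#' every replicate. Replicate folds are averaged; the SEM across replicates
#' is reported. Any non-untreated condition (induced, or induced after drug
#' preincubation) is normalized against the same untreated baseline.
#'
#' @param norm_table output of [delta_ct()].
#' @param untreated name of the baseline condition (default `"untreated"`).
#' @return data.frame `amplicon_id, role, condition, fold_change, sem,
#'   n_replicates`.
#' @export
fold_change <- function(norm_table, untreated = "untreated") {
  dt <- data.table::as.data.table(norm_table)
  stopifnot("dct" %in% names(dt))
  if (!untreated %in% dt$condition)
    stop("baseline condition '", untreated, "' absent from table")
  base <- dt[condition == untreated,
             .(amplicon_id, replicate, dct_base = dct)]
  j <- base[dt, on = c("amplicon_id", "replicate")]
  if (anyNA(j$dct_base))
    stop("unpaired replicate(s): untreated baseline missing for some ",
         "(amplicon, replicate)")
  j[, fold := 2^(-(dct - dct_base))]
  out <- j[, .(fold_change = mean(fold),
               sem = if (.N > 1) sd(fold) / sqrt(.N) else 0,
               n_replicates = .N),
           by = .(amplicon_id, role, condition)]
  setorder(out, condition, amplicon_id)
  as.data.frame(out)
}

#' Percent DSB from fold-changes
#'
#' Converts retained-template fold-changes into percent cleaved alleles:
#' `percent_dsb = (1 - fold_change) * 100`. The untreated baseline (fold 1)
#' maps to 0%; values may be negative (signal gain) and are reported
#' unclamped. In a noise-free simulation an amplicon spanning a site with
#' cut fraction `f` returns exactly `100 * f`.
#'
#' @param folds output of [fold_change()].
#' @return data.frame of DSB estimates with `percent_dsb` and `sem_percent`
#'   (SEM propagated: 100 x SEM of the fold).
#' @export
percent_dsb <- function(folds) {
  stopifnot(all(c("amplicon_id", "fold_change") %in% names(folds)))
  out <- folds
  out$percent_dsb <- (1 - out$fold_change) * 100
  out$sem_percent <- 100 * out$sem
  out
}

#' Full Ct-to-%DSB pipeline
#'
#' Convenience wrapper: [delta_ct()] then [fold_change()] then
#' [percent_dsb()]. With two housekeeping genes the default normalizes to
#' their mean; per-housekeeping results are attached for transparency.
#'
#' @param ct_table CtTable data.frame or CSV path.
#' @param housekeeping_id optional single housekeeping amplicon.
#' @param untreated baseline condition name.
#' @return data.frame of DSB estimates; attribute `"per_housekeeping"`
#'   holds a named list of the same estimates computed with each
#'   housekeeping amplicon alone.
#' @export
quantify_dsb <- function(ct_table, housekeeping_id = NULL,
                         untreated = "untreated") {
  if (is.character(ct_table)) ct_table <- read_ct_table(ct_table)
  est <- percent_dsb(fold_change(delta_ct(ct_table, housekeeping_id),
                                 untreated))
  if (is.null(housekeeping_id)) {
    hks <- unique(ct_table$amplicon_id[ct_table$role == "housekeeping"])
    if (length(hks) > 1) {
      per <- lapply(hks, function(h)
        percent_dsb(fold_change(delta_ct(ct_table, h), untreated)))
      names(per) <- hks
      attr(est, "per_housekeeping") <- per
    }
  }
  est
}
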