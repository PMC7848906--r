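# Iron-sensitivity classification: an OTU is iron-sensitive if it was
# present at appreciable levels at baseline and became undetectable in more
# than half of the mice during the low-iron phase; a sensitive OTU is
# "recovered" if it was detected again in enough mice at any repletion time
# point. Detection limit = >= 1 read in the rarefied table.

#' Classify OTUs as iron-sensitive / recovered
#'
#' Per mouse, an OTU is "undetectable during LI" if it has zero reads at
#' every LI time point sampled for that mouse (mice with no LI samples are
#' excluded from the denominator). An OTU is sensitive iff it is appreciable
#' at baseline — detected in at least `appreciable_min_prevalence` of
#' baseline samples and with mean baseline relative abundance at least
#' `appreciable_min_relabund` — and undetectable in strictly more than
#' `undetectable_frac` of the LI-sampled mice. A sensitive OTU is recovered
#' iff detected at any repletion time point in at least
#' `recovery_min_prevalence` of the repletion-sampled mice.
#'
#' @param table rarefied `OTUTable`.
#' @param metadata [sample_metadata()].
#' @param baseline_tps,li_tps,repletion_tps non-overlapping time-point sets
#'   (defaults `B7`/`B14`, `LI7`/`LI14`, `R7`/`R14`). `repletion_tps` may be
#'   empty/absent, in which case recovery is `NA` and statuses are limited
#'   to sensitive / unaffected.
#' @param appreciable_min_prevalence minimum fraction of baseline samples
#'   with detection (default 0.5).
#' @param appreciable_min_relabund minimum mean baseline relative abundance
#'   (default 0.001, i.e. 10 reads at depth 10,000).
#' @param undetectable_frac an OTU must be undetectable in strictly more
#'   than this fraction of mice during LI (default 0.5).
#' @param recovery_min_prevalence minimum fraction of mice with repletion
#'   detection for "recovered" (default 0.5).
#' @return data.frame of class `SensitivityCalls`: `otu_id`, `status`
#'   (`sensitive_recovered` / `sensitive_not_recovered` / `unaffected`),
#'   `baseline_prevalence`, `baseline_mean_relabund`,
#'   `li_undetectable_frac`, `repletion_prevalence`.
#' @export
classify_sensitivity <- function(table, metadata,
                                 baseline_tps = c("B7", "B14"),
                                 li_tps = c("LI7", "LI14"),
                                 repletion_tps = c("R7", "R14"),
                                 appreciable_min_prevalence = 0.5,
                                 appreciable_min_relabund = 0.001,
                                 undetectable_frac = 0.5,
                                 recovery_min_prevalence = 0.5) {
  stopifnot(inherits(table, "OTUTable"))
  sets <- list(baseline_tps, li_tps, repletion_tps)
  if (anyDuplicated(unlist(sets)))
    stop("baseline, LI and repletion time-point sets must not overlap")
  md <- metadata[metadata$sample_id %in% table$sample_ids, , drop = FALSE]
  m <- table$counts[md$sample_id, , drop = FALSE]
  relab <- relative_abundance(m)
  tp <- as.character(md$timepoint)

  base_rows <- which(tp %in% baseline_tps)
  li_rows <- which(tp %in% li_tps)
  rep_rows <- which(tp %in% repletion_tps)
  if (!length(base_rows)) stop("no samples at baseline time points")
  if (!length(li_rows)) stop("no samples at LI time points")
  has_repletion <- length(rep_rows) > 0

  # per-mouse detection aggregation over a row set: detected anywhere /
  # detected nowhere, over the mice that have samples in the set
  per_mouse_any <- function(rows) {
    mice <- unique(md$mouse_id[rows])
    det <- vapply(mice, function(mm) {
      r <- rows[md$mouse_id[rows] == mm]
      colSums(m[r, , drop = FALSE] >= 1) > 0
    }, logical(ncol(m)))
    t(det)  # mice x OTUs
  }
  # baseline prevalence is sample-level (fraction of baseline samples with
  # detection), the conventional definition; per-mouse aggregation applies
  # only to the LI and repletion criteria below
  baseline_prevalence <- colMeans(m[base_rows, , drop = FALSE] >= 1)
  baseline_mean_relabund <- colMeans(relab[base_rows, , drop = FALSE])

  li_det <- per_mouse_any(li_rows)          # detected at >= 1 LI time point
  li_undetectable_frac <- colMeans(!li_det) # zero at every sampled LI tp

  repletion_prevalence <- if (has_repletion)
    colMeans(per_mouse_any(rep_rows)) else rep(NA_real_, ncol(m))

  appreciable <- baseline_prevalence >= appreciable_min_prevalence &
    baseline_mean_relabund >= appreciable_min_relabund
  sensitive <- appreciable & li_undetectable_frac > undetectable_frac
  status <- rep("unaffected", ncol(m))
  if (has_repletion) {
    recovered <- repletion_prevalence >= recovery_min_prevalence
    status[sensitive & recovered] <- "sensitive_recovered"
    status[sensitive & !recovered] <- "sensitive_not_recovered"
  } else {
    status[sensitive] <- "sensitive"
  }
  out <- data.frame(
    otu_id = colnames(m), status = status,
    baseline_prevalence = baseline_prevalence,
    baseline_mean_relabund = baseline_mean_relabund,
    li_undetectable_frac = li_undetectable_frac,
    repletion_prevalence = repletion_prevalence,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("SensitivityCalls", "data.frame")
  out
}
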