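# The benchmark: score a selection technique by how much deleting its OTUs
# reduces the PERMANOVA pseudo-F across a treatment transition, and by how
# few OTUs it needed. After removal, samples are NOT re-rarefied:
# Bray-Curtis is recomputed on the remaining counts, so F differences
# reflect composition alone, and F_full / F_reduced share the same
# permutation seed.

#' Evaluate an OTU selection by pseudo-F reduction
#'
#' @param table rarefied `OTUTable`.
#' @param metadata [sample_metadata()].
#' @param transition length-2 character: the two time points compared.
#' @param selection a `SelectionResult`, or a character vector of OTU ids.
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param seed permutation seed, shared by the full and reduced tests.
#' @return object of class `EvaluationRecord`: `method`, `group`,
#'   `transition`, `n_selected`, `F_full`, `F_reduced`, `delta_F`, `p_full`,
#'   `p_reduced`.
#' @export
evaluate_selection <- function(table, metadata, transition, selection,
                               n_permutations = 999, seed = 1L) {
  stopifnot(length(transition) == 2)
  sel_ids <- if (inherits(selection, "SelectionResult")) selection$selected
             else as.character(selection)
  method <- if (inherits(selection, "SelectionResult")) selection$method
            else "custom"
  ts <- transition_subset(table, metadata, transition[1], transition[2])
  m <- ts$table$counts
  unknown <- setdiff(sel_ids, colnames(m))
  if (length(unknown))
    stop("selection contains OTUs absent from table: ",
         paste(head(unknown, 5), collapse = ", "))
  if (length(sel_ids) == ncol(m))
    stop("selection removes every OTU")
  dm_full <- distance_matrix(m)
  full <- permanova(dm_full, ts$labels, n_permutations = n_permutations,
                    seed = seed)
  if (length(sel_ids) == 0) {
    reduced <- full
  } else {
    m_red <- m[, setdiff(colnames(m), sel_ids), drop = FALSE]
    reduced <- permanova(distance_matrix(m_red), ts$labels,
                         n_permutations = n_permutations, seed = seed)
  }
  grp <- unique(ts$metadata$group)
  structure(
    list(method = method,
         group = if (length(grp) == 1) grp else "pooled",
         transition = transition, n_selected = length(sel_ids),
         F_full = full$pseudo_F, F_reduced = reduced$pseudo_F,
         delta_F = full$pseudo_F - reduced$pseudo_F,
         p_full = full$p_value, p_reduced = reduced$p_value,
         n_permutations = n_permutations, seed = seed),
    class = "EvaluationRecord")
}

#' @export
print.EvaluationRecord <- function(x, ...) {
  cat(sprintf(
    "[%s] %s -> %s (%s): %d OTU(s); F %.3g -> %.3g (delta %.3g); p %.3g -> %.3g\n",
    x$method, x$transition[1], x$transition[2], x$group, x$n_selected,
    x$F_full, x$F_reduced, x$delta_F, x$p_full, x$p_reduced))
  invisible(x)
}

#' Bind evaluation records into a tidy data.frame
#'
#' @param records list of `EvaluationRecord`s.
#' @return data.frame, one row per record.
#' @export
evaluation_table <- function(records) {
  do.call(rbind, lapply(records, function(r) data.frame(
    method = r$method, group = r$group,
    transition = paste(r$transition, collapse = "->"),
    n_selected = r$n_selected, F_full = r$F_full, F_reduced = r$F_reduced,
    delta_F = r$delta_F, p_full = r$p_full, p_reduced = r$p_reduced,
    stringsAsFactors = FALSE)))
}

#' Compare selection techniques across groups and transitions
#'
#' For every technique pair, a paired t-test on the pseudo-F reduction
#' (`delta_F`) and on the number of selected OTUs, paired by
#' (experimental group, transition); unmatched pairs are dropped with a
#' warning. Techniques are also ranked by median `delta_F` (descending) and
#' median `n_selected` (ascending).
#'
#' @param records list of `EvaluationRecord`s or an [evaluation_table()]
#'   data.frame.
#' @return list of class `TechniqueComparison`: `summary` (per-technique
#'   medians and ranks) and `pairwise` (per-pair paired t-tests).
#' @export
compare_techniques <- function(records) {
  df <- if (is.data.frame(records)) records else evaluation_table(records)
  df$unit <- paste(df$group, df$transition, sep = "|")
  methods <- sort(unique(df$method))
  if (length(methods) < 2) stop("need records from >= 2 techniques")

  summary <- do.call(rbind, lapply(methods, function(m) {
    sub <- df[df$method == m, ]
    data.frame(method = m, n_records = nrow(sub),
               median_delta_F = median(sub$delta_F),
               median_n_selected = median(sub$n_selected),
               stringsAsFactors = FALSE)
  }))
  summary <- summary[order(-summary$median_delta_F,
                           summary$median_n_selected), ]
  summary$rank_delta_F <- rank(-summary$median_delta_F, ties.method = "min")
  summary$rank_n_selected <- rank(summary$median_n_selected,
                                  ties.method = "min")
  rownames(summary) <- NULL

  pairs <- utils::combn(methods, 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    a <- df[df$method == pr[1], ]
    b <- df[df$method == pr[2], ]
    units <- intersect(a$unit, b$unit)
    dropped <- length(union(a$unit, b$unit)) - length(units)
    if (dropped > 0)
      warning(sprintf("%d unmatched (group, transition) unit(s) dropped for %s vs %s",
                      dropped, pr[1], pr[2]))
    da <- a$delta_F[match(units, a$unit)]
    db <- b$delta_F[match(units, b$unit)]
    na_ <- a$n_selected[match(units, a$unit)]
    nb <- b$n_selected[match(units, b$unit)]
    tt <- function(x, y) {
      if (length(x) < 2 || sd(x - y) == 0)
        return(c(stat = if (all(x == y)) 0 else NA_real_,
                 p = if (all(x == y)) 1 else NA_real_))
      r <- t.test(x, y, paired = TRUE)
      c(stat = unname(r$statistic), p = r$p.value)
    }
    t_dF <- tt(da, db); t_n <- tt(na_, nb)
    data.frame(method_a = pr[1], method_b = pr[2], n_pairs = length(units),
               mean_delta_F_diff = mean(da - db), t_delta_F = t_dF[["stat"]],
               p_delta_F = t_dF[["p"]], mean_n_selected_diff = mean(na_ - nb),
               t_n_selected = t_n[["stat"]], p_n_selected = t_n[["p"]],
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, pairwise = pairwise),
            class = "TechniqueComparison")
}

#' @export
print.TechniqueComparison <- function(x, ...) {
  cat("Technique ranking (by median pseudo-F reduction):\n")
  print(x$summary, row.names = FALSE)
  cat("\nPairwise paired t-tests:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
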