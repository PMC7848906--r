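# The four OTU-selection techniques compared by the benchmark: random-forest
# permutation importance with a null-calibrated threshold, indicator value
# (IndVal) analysis with a permutation test, presence-absence prevalence
# screening, and per-OTU multiple t testing with multiplicity correction.
# All techniques operate on relative abundances (rarefied tables have
# constant depth, so proportions and counts carry the same information).

new_selection_result <- function(method, scores, selected, parameters,
                                 seed = NA_integer_, transition = NULL) {
  stopifnot(all(selected %in% scores$otu_id))
  structure(
    list(method = method, transition = transition, selected = selected,
         scores = scores, parameters = parameters, seed = seed),
    class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf("SelectionResult [%s]%s: %d OTU(s) selected of %d\n",
              x$method,
              if (is.null(x$transition)) ""
              else paste0(" ", paste(x$transition, collapse = " -> ")),
              length(x$selected), nrow(x$scores)))
  if (length(x$selected))
    cat(" ", paste(head(x$selected, 10), collapse = ", "),
        if (length(x$selected) > 10) "..." else "", "\n")
  invisible(x)
}

.two_class <- function(labels, min_per_class = 1) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2)
    stop("labels must contain exactly two classes, got: ",
         paste(lev, collapse = ", "))
  n <- table(labels)
  if (any(n < min_per_class))
    stop("each class needs >= ", min_per_class, " samples")
  factor(labels, levels = lev)
}

#' Random-forest OTU selection
#'
#' Trains a random-forest classifier separating the two time points on
#' relative abundances and computes per-OTU out-of-bag permutation
#' importance. The selection threshold is calibrated against the null: the
#' forest is refit on `importance_null_reps` label-shuffled copies of the
#' data, and OTUs whose observed importance exceeds the `(1 - alpha)`
#' quantile of the null maximum importances are selected (controlling the
#' familywise false-selection rate at about `alpha`). `top_k` switches to a
#' plain top-k ranking instead.
#'
#' @param table `OTUTable` or counts matrix.
#' @param labels two-class label per sample (the two time points).
#' @param n_trees trees per forest (default 500).
#' @param importance_null_reps label-shuffled refits for calibration
#'   (default 99).
#' @param alpha familywise false-selection level (default 0.05).
#' @param seed integer seed; results are fully reproducible.
#' @param mtry candidate features per split (default `floor(sqrt(p))`).
#' @param top_k if non-`NULL`, skip calibration and select the `top_k` OTUs
#'   by importance.
#' @return a `SelectionResult`; `scores` has columns `otu_id`, `score`
#'   (importance), and for the calibrated mode the threshold is stored in
#'   `parameters`.
#' @export
select_random_forest <- function(table, labels, n_trees = 500,
                                 importance_null_reps = 99, alpha = 0.05,
                                 seed = 1L, mtry = NULL, top_k = NULL) {
  X <- relative_abundance(table)
  X <- X[, order(colnames(X)), drop = FALSE]  # canonical feature order:
  # selection is then invariant to the input table's column order
  y <- .two_class(labels, min_per_class = 2)
  if (length(y) != nrow(X)) stop("labels length must match sample count")
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  y01 <- as.integer(y) - 1L
  set.seed(seed)
  obs <- .rf_importance(X, y01, n_trees, as.integer(mtry), 1L)
  imp <- as.numeric(obs$importance)
  names(imp) <- colnames(X)
  scores <- data.frame(otu_id = colnames(X), score = imp,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(top_k)) {
    sel <- scores$otu_id[order(scores$score, decreasing = TRUE)][seq_len(
      min(top_k, p))]
    return(new_selection_result(
      "random_forest", scores, sel,
      list(n_trees = n_trees, mtry = mtry, mode = "top_k", top_k = top_k),
      seed))
  }
  null_max <- vapply(seq_len(importance_null_reps), function(r) {
    y_perm <- y01[sample.int(length(y01))]
    max(as.numeric(.rf_importance(X, y_perm, n_trees,
                                  as.integer(mtry), 1L)$importance))
  }, numeric(1))
  threshold <- as.numeric(quantile(null_max, 1 - alpha))
  sel_idx <- which(imp > threshold)
  sel <- scores$otu_id[sel_idx][order(imp[sel_idx], decreasing = TRUE)]
  new_selection_result(
    "random_forest", scores, sel,
    list(n_trees = n_trees, mtry = mtry, mode = "null_calibrated",
         alpha = alpha, importance_null_reps = importance_null_reps,
         threshold = threshold, oob_error = obs$oob_error),
    seed)
}

# IndVal components for a relative-abundance matrix and a grouping factor:
# A (specificity) = group mean relative abundance / sum over groups;
# B (fidelity) = fraction of the group's samples where the OTU is present.
# Returns max over groups of A * B * 100 per OTU.
.indval_scores <- function(relab, groups) {
  lev <- levels(groups)
  gm <- t(vapply(lev, function(g)
    colMeans(relab[groups == g, , drop = FALSE]), numeric(ncol(relab))))
  gb <- t(vapply(lev, function(g)
    colMeans(relab[groups == g, , drop = FALSE] > 0), numeric(ncol(relab))))
  tot <- colSums(gm)
  A <- sweep(gm, 2, ifelse(tot > 0, tot, 1), "/")
  A[, tot == 0] <- 0
  iv <- A * gb * 100
  apply(iv, 2, max)
}

#' Indicator-value (IndVal) OTU selection
#'
#' For each OTU and group, the indicator value is specificity x fidelity x
#' 100: `A = mean relative abundance in the group / sum of group means`
#' times `B = fraction of the group's samples where the OTU is present`.
#' The OTU's score is the maximum over groups; significance comes from a
#' group-label permutation test (add-one convention), and p-values are
#' BH-adjusted within the technique.
#'
#' @param table `OTUTable` or counts matrix.
#' @param labels group label per sample (two time points).
#' @param n_permutations label permutations (default 999).
#' @param alpha selection level on the BH-adjusted p (default 0.05).
#' @param seed integer seed.
#' @return a `SelectionResult`; `scores` has `otu_id`, `score` (IndVal on
#'   the 0-100 scale), `p_raw`, `p_adjusted`.
#' @export
select_indval <- function(table, labels, n_permutations = 999, alpha = 0.05,
                          seed = 1L) {
  X <- relative_abundance(table)
  groups <- .two_class(labels)
  obs <- .indval_scores(X, groups)
  set.seed(seed)
  exceed <- integer(length(obs))
  for (b in seq_len(n_permutations)) {
    perm <- groups[sample.int(length(groups))]
    exceed <- exceed + (.indval_scores(X, perm) >= obs - 1e-12)
  }
  p_raw <- (exceed + 1) / (n_permutations + 1)
  p_adj <- bh_adjust(p_raw)
  scores <- data.frame(otu_id = colnames(X), score = obs, p_raw = p_raw,
                       p_adjusted = p_adj, row.names = NULL,
                       stringsAsFactors = FALSE)
  sel_idx <- which(p_adj < alpha)
  sel <- scores$otu_id[sel_idx][order(obs[sel_idx], decreasing = TRUE)]
  new_selection_result(
    "indval", scores, sel,
    list(n_permutations = n_permutations, alpha = alpha), seed)
}

#' Presence-absence OTU selection
#'
#' Selects OTUs detected (>= 1 read, i.e. above the rarefied detection
#' limit) in more than `prevalence_high` of samples at one time point while
#' detected in at most `prevalence_zero` of samples at the other, in either
#' direction. The score is the absolute prevalence difference.
#'
#' @param table `OTUTable` or counts matrix.
#' @param labels two-class label per sample.
#' @param prevalence_high prevalence that must be exceeded on the "present"
#'   side (default 0.5).
#' @param prevalence_zero maximum prevalence allowed on the "absent" side
#'   (default 0).
#' @return a `SelectionResult`; `scores` has `otu_id`, `score` (|prevalence
#'   delta|), `prevalence_a`, `prevalence_b`.
#' @export
select_presence_absence <- function(table, labels, prevalence_high = 0.5,
                                    prevalence_zero = 0.0) {
  m <- .counts(table)
  groups <- .two_class(labels)
  lev <- levels(groups)
  prev_a <- colMeans(m[groups == lev[1], , drop = FALSE] >= 1)
  prev_b <- colMeans(m[groups == lev[2], , drop = FALSE] >= 1)
  hit <- (prev_a > prevalence_high & prev_b <= prevalence_zero) |
         (prev_b > prevalence_high & prev_a <= prevalence_zero)
  score <- abs(prev_a - prev_b)
  scores <- data.frame(otu_id = colnames(m), score = score,
                       prevalence_a = prev_a, prevalence_b = prev_b,
                       row.names = NULL, stringsAsFactors = FALSE)
  sel <- scores$otu_id[hit][order(score[hit], decreasing = TRUE)]
  new_selection_result(
    "presence_absence", scores, sel,
    list(prevalence_high = prevalence_high,
         prevalence_zero = prevalence_zero), NA_integer_)
}

#' Multiple-t-test OTU selection
#'
#' Per-OTU t-test on relative abundances between the two time points —
#' paired across mice when subject pairing is supplied — with Bonferroni
#' (default, the benchmark convention) or Benjamini-Hochberg correction.
#' By default abundances are log10-transformed with a pseudocount of half
#' the detection limit (`0.5 / depth`), the standard variance-stabilizing
#' choice for compositional count data; `transform = "none"` tests raw
#' proportions. OTUs with no variation (including all-zero OTUs) are
#' skipped with `NA` and never selected.
#'
#' @param table `OTUTable` or counts matrix.
#' @param labels two-class label per sample.
#' @param correction `"bonferroni"` or `"bh"`.
#' @param alpha selection level on the adjusted p (default 0.05).
#' @param paired pair observations across the two classes by `subjects`.
#' @param subjects subject (mouse) id per sample; required when
#'   `paired = TRUE`.
#' @param transform `"log10"` (default) or `"none"`.
#' @param var_equal pooled-variance t-test instead of Welch (default Welch).
#' @return a `SelectionResult`; `scores` has `otu_id`, `score` (adjusted p),
#'   `statistic`, `p_raw`, `p_adjusted`.
#' @export
select_multiple_ttest <- function(table, labels,
                                  correction = c("bonferroni", "bh"),
                                  alpha = 0.05, paired = FALSE,
                                  subjects = NULL,
                                  transform = c("log10", "none"),
                                  var_equal = FALSE) {
  correction <- match.arg(correction)
  transform <- match.arg(transform)
  X <- relative_abundance(table)
  if (transform == "log10") {
    depth <- median(rowSums(.counts(table)))
    X <- log10(X + 0.5 / depth)
  }
  groups <- .two_class(labels, min_per_class = 2)
  lev <- levels(groups)
  ia <- groups == lev[1]; ib <- groups == lev[2]
  if (paired) {
    if (is.null(subjects)) stop("paired = TRUE requires subjects")
    common <- intersect(subjects[ia], subjects[ib])
    if (length(common) < 2) stop("need >= 2 complete pairs")
    A <- X[ia, , drop = FALSE][match(common, subjects[ia]), , drop = FALSE]
    B <- X[ib, , drop = FALSE][match(common, subjects[ib]), , drop = FALSE]
  }
  stat <- p_raw <- rep(NA_real_, ncol(X))
  for (j in seq_len(ncol(X))) {
    res <- tryCatch({
      if (paired) t.test(A[, j], B[, j], paired = TRUE)
      else t.test(X[ia, j], X[ib, j], var.equal = var_equal)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      stat[j] <- unname(res$statistic)
      p_raw[j] <- res$p.value
    }
  }
  ok <- !is.na(p_raw)
  p_adj <- rep(NA_real_, ncol(X))
  p_adj[ok] <- if (correction == "bonferroni") bonferroni_adjust(p_raw[ok])
               else bh_adjust(p_raw[ok])
  scores <- data.frame(otu_id = colnames(X), score = p_adj, statistic = stat,
                       p_raw = p_raw, p_adjusted = p_adj, row.names = NULL,
                       stringsAsFactors = FALSE)
  sel_idx <- which(!is.na(p_adj) & p_adj < alpha)
  sel <- scores$otu_id[sel_idx][order(p_adj[sel_idx])]
  new_selection_result(
    "multiple_ttest", scores, sel,
    list(correction = correction, alpha = alpha, paired = paired,
         transform = transform, var_equal = var_equal), NA_integer_)
}

#' Build two-time-point labels from metadata
#'
#' @param table `OTUTable`.
#' @param metadata [sample_metadata()].
#' @param from,to the two time points of the transition.
#' @return list: `table` (subset to the transition's samples), `labels`
#'   (factor with levels `from`, `to`), `subjects` (mouse ids).
#' @export
transition_subset <- function(table, metadata, from, to) {
  keep <- metadata$timepoint %in% c(from, to) &
    metadata$sample_id %in% table$sample_ids
  md <- metadata[keep, , drop = FALSE]
  if (!nrow(md)) stop("no samples at time points ", from, "/", to)
  sub <- subset_table(table, samples = md$sample_id)
  list(table = sub,
       labels = factor(as.character(md$timepoint), levels = c(from, to)),
       subjects = md$mouse_id, metadata = md)
}

#' Run one selection technique on a treatment transition
#'
#' Front end used by the pipeline and CLI: subsets the table to the two time
#' points and dispatches to the technique.
#'
#' @param table `OTUTable`.
#' @param metadata [sample_metadata()].
#' @param from,to the transition's time points.
#' @param method one of `"rf"`, `"indval"`, `"presence"`, `"ttest"`.
#' @param ... passed to the technique.
#' @return a `SelectionResult` with `transition = c(from, to)`.
#' @export
select_otus <- function(table, metadata, from, to,
                        method = c("rf", "indval", "presence", "ttest"),
                        ...) {
  method <- match.arg(method)
  ts <- transition_subset(table, metadata, from, to)
  res <- switch(method,
    rf = select_random_forest(ts$table, ts$labels, ...),
    indval = select_indval(ts$table, ts$labels, ...),
    presence = select_presence_absence(ts$table, ts$labels, ...),
    ttest = select_multiple_ttest(ts$table, ts$labels, paired = TRUE,
                                  subjects = ts$subjects, ...))
  res$transition <- c(from, to)
  res
}
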