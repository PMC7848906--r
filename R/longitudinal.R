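# Paired nonparametric time-point comparisons, multiplicity corrections and
# the comparative threshold-cycle (Ct) relative-expression estimator.

#' Paired Wilcoxon signed-rank test
#'
#' The paired nonparametric comparison of two time points: within-subject
#' differences are ranked by absolute value, zero differences dropped, and
#' the positive-rank sum `W+` tested two-sided. The exact null distribution
#' (sign enumeration) is used when `n <= 25` and there are no ties among the
#' absolute differences; otherwise a normal approximation with continuity
#' correction and tie-corrected variance is used.
#'
#' @param values_a,values_b measurements at the two time points.
#' @param subjects subject id per element; pairs are formed by subject and
#'   subjects missing either time point are dropped. If `NULL`, elements are
#'   paired positionally.
#' @return list with `statistic` (W+), `p_value`, `n_pairs` (non-zero
#'   differences used), `method` (`"exact"` or `"normal"`). If every
#'   difference is zero, `statistic = 0` and `p_value = NA` with
#'   `method = "degenerate"`.
#' @export
paired_wilcoxon <- function(values_a, values_b, subjects = NULL) {
  if (!is.null(subjects)) {
    if (length(subjects) != length(values_a) ||
        length(values_a) != length(values_b))
      stop("values_a, values_b and subjects must have equal length")
    ok_a <- !is.na(values_a); ok_b <- !is.na(values_b)
    sub <- unique(subjects)
    a <- setNames(rep(NA_real_, length(sub)), sub)
    b <- a
    a[subjects[ok_a]] <- values_a[ok_a]
    b[subjects[ok_b]] <- values_b[ok_b]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep))
      stop("no complete pairs; subjects missing a time point: ",
           paste(sub[!keep], collapse = ", "))
    d <- a[keep] - b[keep]
  } else {
    if (length(values_a) != length(values_b))
      stop("values_a and values_b must have equal length")
    keep <- !is.na(values_a) & !is.na(values_b)
    if (!any(keep)) stop("no complete pairs")
    d <- values_a[keep] - values_b[keep]
  }
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p_value = NA_real_, n_pairs = 0L,
                method = "degenerate"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (n <= 25 && !ties) {
    p <- 2 * min(psignrank(W, n), psignrank(W - 1, n, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, p_value = p, n_pairs = n, method = method)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1, returned in input
#' order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  .check_p(p_values)
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values, decreasing = TRUE)
  q <- pmin(1, cummin(p_values[o] * m / seq(m, 1)))
  q[order(o)]
}

#' Bonferroni adjustment
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return `min(1, p * m)` elementwise.
#' @export
bonferroni_adjust <- function(p_values) {
  .check_p(p_values)
  pmin(1, p_values * length(p_values))
}

.check_p <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
}

#' Run a family of sequential paired comparisons with BH correction
#'
#' Compares each consecutive pair of time points for one measurement (e.g.
#' inverse Simpson, stool iron), pairing by mouse, and adjusts the family of
#' raw p-values by Benjamini-Hochberg.
#'
#' @param values named-by-nothing numeric vector of measurements.
#' @param metadata [sample_metadata()] rows aligned with `values`.
#' @param timepoints time points to compare sequentially; defaults to those
#'   present, in factor order.
#' @return data.frame: `timepoint_a`, `timepoint_b`, `n_pairs`, `statistic`,
#'   `p_raw`, `p_adjusted`, `method`.
#' @export
sequential_paired_tests <- function(values, metadata, timepoints = NULL) {
  stopifnot(length(values) == nrow(metadata))
  if (is.null(timepoints))
    timepoints <- levels(droplevels(metadata$timepoint))
  if (length(timepoints) < 2) stop("need >= 2 time points")
  rows <- list()
  for (i in seq_len(length(timepoints) - 1)) {
    ta <- timepoints[i]; tb <- timepoints[i + 1]
    ia <- which(metadata$timepoint == ta)
    ib <- which(metadata$timepoint == tb)
    mice <- union(metadata$mouse_id[ia], metadata$mouse_id[ib])
    va <- setNames(rep(NA_real_, length(mice)), mice)
    vb <- va
    va[metadata$mouse_id[ia]] <- values[ia]
    vb[metadata$mouse_id[ib]] <- values[ib]
    w <- tryCatch(paired_wilcoxon(va, vb, subjects = mice),
                  error = function(e) list(statistic = NA_real_,
                                           p_value = NA_real_, n_pairs = 0L,
                                           method = "none"))
    rows[[i]] <- data.frame(timepoint_a = ta, timepoint_b = tb,
                            n_pairs = w$n_pairs, statistic = w$statistic,
                            p_raw = w$p_value, method = w$method,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_raw)
  out$p_adjusted <- NA_real_
  out$p_adjusted[ok] <- bh_adjust(out$p_raw[ok])
  out
}

#' Comparative threshold-cycle (Ct) relative expression
#'
#' Per animal, `dCt = Ct_target - Ct_reference`; across arms,
#' `ddCt = mean dCt(treatment) - mean dCt(control)` and
#' `fold_change = 2^(-ddCt)`. A two-sample t-test (Welch by default) on the
#' per-animal dCt values accompanies the estimate.
#'
#' @param ct_records data.frame with columns `animal`, `tissue`, `gene`,
#'   `ct`, `role` (`"target"`/`"reference"`), `arm`
#'   (`"treatment"`/`"control"`).
#' @param gene target gene to analyse.
#' @param tissue tissue to analyse.
#' @param var_equal pass `TRUE` for the pooled-variance t-test (default
#'   Welch).
#' @return object of class `ExpressionResult`: `gene`, `tissue`,
#'   `fold_change`, `ddct`, `dct_treatment`, `dct_control` (per-animal
#'   vectors), `p_value`.
#' @export
ddct_fold_change <- function(ct_records, gene, tissue, var_equal = FALSE) {
  rec <- ct_records[ct_records$tissue == tissue, , drop = FALSE]
  tgt <- rec[rec$gene == gene & rec$role == "target", , drop = FALSE]
  ref <- rec[rec$role == "reference", , drop = FALSE]
  if (!nrow(ref)) stop("missing reference gene records for tissue ", tissue)
  if (!nrow(tgt)) stop("no target records for gene ", gene)
  dct_by_arm <- lapply(c("treatment", "control"), function(arm) {
    t_arm <- tgt[tgt$arm == arm, , drop = FALSE]
    r_arm <- ref[ref$arm == arm, , drop = FALSE]
    animals <- intersect(t_arm$animal, r_arm$animal)
    if (!length(animals))
      stop("arm '", arm, "' lacks paired target and reference Ct values")
    vapply(animals, function(a) {
      mean(t_arm$ct[t_arm$animal == a]) - mean(r_arm$ct[r_arm$animal == a])
    }, numeric(1))
  })
  names(dct_by_arm) <- c("treatment", "control")
  ddct <- mean(dct_by_arm$treatment) - mean(dct_by_arm$control)
  p <- if (length(dct_by_arm$treatment) > 1 && length(dct_by_arm$control) > 1 &&
           (var(dct_by_arm$treatment) + var(dct_by_arm$control)) > 0)
    t.test(dct_by_arm$treatment, dct_by_arm$control,
           var.equal = var_equal)$p.value
  else NA_real_
  structure(
    list(gene = gene, tissue = tissue, fold_change = 2^(-ddct), ddct = ddct,
         dct_treatment = dct_by_arm$treatment,
         dct_control = dct_by_arm$control, p_value = p),
    class = "ExpressionResult")
}

#' @export
print.ExpressionResult <- function(x, ...) {
  cat(sprintf("%s (%s): fold change = %.3g (ddCt = %.3g), t-test p = %.3g\n",
              x$gene, x$tissue, x$fold_change, x$ddct, x$p_value))
  invisible(x)
}
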