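# One-factor PERMANOVA: partition of squared dissimilarities into between-
# and within-group components, with the pseudo-F ratio tested by label
# permutation (add-one convention) or by complete enumeration.

.ss_partition <- function(d2, grouping) {
  n <- nrow(d2)
  ut <- upper.tri(d2)
  ss_total <- sum(d2[ut]) / n
  ss_within <- 0
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

.pseudo_F <- function(d2, grouping, a, n) {
  ss <- .ss_partition(d2, grouping)
  if (ss[["within"]] == 0) return(Inf)
  (ss[["between"]] / (a - 1)) / (ss[["within"]] / (n - a))
}

# all permutations of seq_len(n) (n <= 8 in practice)
.all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 1L
  for (i in seq_len(n)) {
    for (p in sub) {
      q <- integer(n)
      q[i] <- n
      q[-i] <- p
      out[[k]] <- q
      k <- k + 1L
    }
  }
  out
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions squared dissimilarities: `SS_total = (1/N) * sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2`,
#' `SS_between = SS_total - SS_within`, and tests
#' `F = (SS_between/(a-1)) / (SS_within/(N-a))` by free permutation of the
#' group labels. With `method = "permutation"` the p-value uses the add-one
#' convention `p = (#{F_perm >= F_obs} + 1) / (n_permutations + 1)`; with
#' `method = "exact"` all label permutations are enumerated and
#' `p = #{F_perm >= F_obs} / #permutations` (the identity included).
#'
#' @param dm symmetric dissimilarity matrix (ids as dimnames) or `dist`.
#' @param grouping one label per sample, in `dm` order (or named by sample
#'   id, in which case it is aligned).
#' @param n_permutations number of random permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param method `"permutation"` or `"exact"` (complete enumeration;
#'   feasible for N <= 9).
#' @param strata optional blocking factor; permutations are then restricted
#'   to shuffles within each stratum (off by default — the conventional free
#'   permutation is used even for repeated-measures designs).
#' @return object of class `PermanovaResult`: `pseudo_F`, `p_value`,
#'   `df_between`, `df_within`, `ss_total`, `ss_between`, `ss_within`,
#'   `n_permutations`, `seed`, `method`.
#' @export
permanova <- function(dm, grouping, n_permutations = 999, seed = 1L,
                      method = c("permutation", "exact"), strata = NULL) {
  method <- match.arg(method)
  d <- as.matrix(dm)
  n <- nrow(d)
  grouping <- if (!is.null(names(grouping)) && !is.null(rownames(d)))
    grouping[rownames(d)] else grouping
  if (length(grouping) != n) stop("grouping length must match dm")
  if (anyNA(grouping)) stop("grouping does not cover all dm ids")
  grouping <- as.character(grouping)
  a <- length(unique(grouping))
  if (a < 2) stop("PERMANOVA needs >= 2 groups")
  if (n - a < 1) stop("no within-group degrees of freedom")
  d2 <- d * d
  ss <- .ss_partition(d2, grouping)
  F_obs <- if (ss[["within"]] == 0) Inf else
    (ss[["between"]] / (a - 1)) / (ss[["within"]] / (n - a))
  tol <- 1e-12
  if (method == "exact") {
    if (n > 9) stop("exact enumeration limited to N <= 9")
    perms <- .all_perms(n)
    Fs <- vapply(perms, function(p) .pseudo_F(d2, grouping[p], a, n), numeric(1))
    p_value <- mean(Fs >= F_obs - tol)
    n_permutations <- length(perms)
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- if (is.null(strata)) sample.int(n) else {
        p <- seq_len(n)
        for (s in unique(strata)) {
          idx <- which(strata == s)
          p[idx] <- idx[sample.int(length(idx))]
        }
        p
      }
      if (.pseudo_F(d2, grouping[perm], a, n) >= F_obs - tol) hits <- hits + 1L
    }
    p_value <- (hits + 1) / (n_permutations + 1)
  }
  structure(
    list(pseudo_F = F_obs, p_value = p_value,
         df_between = a - 1L, df_within = n - a,
         ss_total = ss[["total"]], ss_between = ss[["between"]],
         ss_within = ss[["within"]],
         n_permutations = n_permutations, seed = seed, method = method),
    class = "PermanovaResult")
}

#' @export
print.PermanovaResult <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g (df %d, %d), p = %.4g (%s, %d permutations)\n",
    x$pseudo_F, x$df_between, x$df_within, x$p_value, x$method,
    x$n_permutations))
  invisible(x)
}
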