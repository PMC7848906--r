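# Nonmetric multidimensional scaling: rank-based embedding minimizing
# Kruskal stress-1, run from multiple starts (metric-scaling start plus
# random configurations) with the best kept. The iterative engine is
# vegan::monoMDS (global model, weak ties), the same engine the field's
# standard workflow uses.

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' @param dm symmetric dissimilarity matrix or `dist`.
#' @param k embedding dimension (default 2).
#' @param n_starts number of starts: one principal-coordinates start plus
#'   `n_starts - 1` random configurations (default 20).
#' @param max_iter maximum iterations per start (default 300).
#' @param tol stress-based convergence threshold (default 1e-6).
#' @param seed integer seed for the random starts.
#' @return object of class `Ordination`: `ids`, `points` (n x k, centred),
#'   `stress` (Kruskal stress-1), `n_starts`, `converged`. Degenerate inputs
#'   (e.g. all dissimilarities equal) yield `converged = FALSE` rather than
#'   an error.
#' @export
nmds <- function(dm, k = 2, n_starts = 20, max_iter = 300, tol = 1e-6,
                 seed = 1L) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (n < k + 1) stop("need at least k + 1 samples")
  dd <- stats::as.dist(d)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- if (s == 1) {
      y <- suppressWarnings(stats::cmdscale(dd, k = k))
      if (ncol(y) < k)  # rank-deficient metric start; pad with jitter
        y <- cbind(y, matrix(rnorm(n * (k - ncol(y)), sd = 1e-4),
                             nrow = n))
      y
    } else {
      matrix(stats::runif(n * k, -1, 1), nrow = n)
    }
    fit <- tryCatch(
      vegan::monoMDS(dd, y = init, k = k, model = "global", maxit = max_iter,
                     smin = tol, sfgrmin = 1e-7),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) {
    return(structure(
      list(ids = rownames(d),
           points = matrix(0, n, k, dimnames = list(rownames(d), NULL)),
           stress = NA_real_, n_starts = n_starts, converged = FALSE),
      class = "Ordination"))
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(d)
  # monoMDS icause: 1 = stress minimum, 2 = stress ratio, 3 = gradient
  # minimum reached (all proper convergence); 4 = iteration limit
  structure(
    list(ids = rownames(d), points = pts, stress = best$stress,
         n_starts = n_starts,
         converged = isTRUE(best$icause %in% 1:3) && is.finite(best$stress)),
    class = "Ordination")
}

#' @export
print.Ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d samples, k = %d, stress-1 = %.4g (%s)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Write NMDS coordinates as TSV
#'
#' @param ord an `Ordination`.
#' @param path output path.
#' @export
write_ordination <- function(ord, path) {
  df <- data.frame(sample_id = ord$ids, ord$points, check.names = FALSE)
  names(df)[-1] <- paste0("NMDS", seq_len(ncol(ord$points)))
  df$stress <- ord$stress
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
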