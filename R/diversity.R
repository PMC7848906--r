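# Alpha diversity (inverse Simpson, richness) and Bray-Curtis beta
# diversity. Summation order is fixed (ascending OTU index) so results are
# bit-reproducible.

#' Inverse Simpson index of one sample
#'
#' The plug-in estimator `1 / sum(p_i^2)` with `p_i = n_i / N`: the effective
#' number of equally abundant taxa. The unbiased finite-sample form
#' `N(N-1) / sum(n_i (n_i - 1))` is available via `unbiased = TRUE`.
#'
#' @param counts non-negative count vector for one sample.
#' @param unbiased use the finite-sample estimator instead of the plug-in
#'   form (default `FALSE`; the plug-in form is the conventional index).
#' @return inverse Simpson index (>= 1).
#' @export
inverse_simpson <- function(counts, unbiased = FALSE) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative counts")
  n <- sum(counts)
  if (n <= 0) stop("inverse Simpson undefined for an all-zero sample")
  if (unbiased) {
    s <- sum(counts * (counts - 1))
    if (s == 0) stop("unbiased inverse Simpson undefined when all counts <= 1")
    return(n * (n - 1) / s)
  }
  p <- counts / n
  1 / sum(p * p)
}

#' Richness (observed OTU count) of one sample
#'
#' @param counts non-negative count vector.
#' @return number of OTUs with count >= 1.
#' @export
richness <- function(counts) {
  sum(counts >= 1)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `sum(|x - y|) / sum(x + y)`, in `[0, 1]`.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  denom <- sum(x + y)
  if (denom == 0) stop("Bray-Curtis undefined for two all-zero samples")
  sum(abs(x - y)) / denom
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param table `OTUTable` or samples x OTUs matrix with >= 2 rows.
#' @return symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
distance_matrix <- function(table) {
  m <- .counts(table)
  n <- nrow(m)
  if (n < 2) stop("need >= 2 samples for a distance matrix")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dij <- tryCatch(bray_curtis(m[i, ], m[j, ]), error = function(e)
        stop(sprintf("samples '%s' vs '%s': %s",
                     rownames(m)[i], rownames(m)[j], conditionMessage(e)),
             call. = FALSE))
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Per-sample diversity summary
#'
#' @param table `OTUTable`.
#' @return data.frame with `sample_id`, `inverse_simpson`, `richness`.
#' @export
diversity_table <- function(table) {
  m <- .counts(table)
  data.frame(
    sample_id = rownames(m),
    inverse_simpson = apply(m, 1, inverse_simpson),
    richness = apply(m, 1, richness),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a distance matrix as TSV or lower-triangle PHYLIP
#'
#' @param d symmetric distance matrix with ids as dimnames.
#' @param path output path.
#' @param format `"tsv"` (square, with header) or `"phylip"`
#'   (lower-triangle).
#' @export
write_distance_matrix <- function(d, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    n <- nrow(d)
    lines <- c(format(n), vapply(seq_len(n), function(i) {
      paste(c(rownames(d)[i],
              if (i > 1) format(d[i, seq_len(i - 1)], digits = 10)),
            collapse = "\t")
    }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}
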