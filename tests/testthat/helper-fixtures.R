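# Shared fixtures, built in code at test time.

# small deterministic OTU table
fix_table <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(50, 30, 20,
                       10,  0, 90,
                        5,  5, 90), nrow = 3, byrow = TRUE)
  }
  rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("Otu%04d", seq_len(ncol(counts)))
  otu_table(counts)
}

fix_metadata <- function(mice = paste0("M", 1:5),
                         timepoints = TIMEPOINT_LEVELS,
                         group = "G1") {
  df <- expand.grid(mouse_id = mice, timepoint = timepoints,
                    stringsAsFactors = FALSE)
  df$sample_id <- paste0(df$mouse_id, "_", df$timepoint)
  df$group <- group
  df$cage <- ifelse(match(df$mouse_id, mice) <= ceiling(length(mice) / 2),
                    "C1", "C2")
  df$sex <- "F"
  sample_metadata(df)
}

# write a small mothur shared file; returns the path
write_fix_shared <- function(lines, path = tempfile(fileext = ".shared")) {
  writeLines(lines, path)
  path
}

# brute-force PERMANOVA oracle: definition-level sums of squares and exact
# p over all label permutations (independent of the package implementation)
oracle_permanova <- function(d, grouping) {
  d <- as.matrix(d)
  n <- nrow(d)
  f_of <- function(g) {
    a <- length(unique(g))
    sst <- 0
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      sst <- sst + d[i, j]^2
    sst <- sst / n
    ssw <- 0
    for (gr in unique(g)) {
      idx <- which(g == gr)
      if (length(idx) > 1) {
        s <- 0
        for (i in seq_along(idx)[-length(idx)])
          for (j in seq(i + 1, length(idx)))
            s <- s + d[idx[i], idx[j]]^2
        ssw <- ssw + s / length(idx)
      }
    }
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  F_obs <- f_of(grouping)
  perms <- ferromic:::.all_perms(n)
  Fs <- vapply(perms, function(p) f_of(grouping[p]), numeric(1))
  list(F = F_obs, p = mean(Fs >= F_obs - 1e-12))
}

# enumeration oracle for the Wilcoxon signed-rank exact two-sided p
oracle_signrank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  W_all <- as.matrix(signs) %*% r
  p_ge <- mean(W_all >= W_obs)
  p_le <- mean(W_all <= W_obs)
  min(1, 2 * min(p_ge, p_le))
}
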