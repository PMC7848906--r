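#' @useDynLib ferromic, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rgamma rnbinom rbinom quantile median sd var
#'   t.test pt qnorm pnorm psignrank complete.cases setNames aggregate
#' @importFrom utils read.delim write.table head modifyList
NULL

#' Ordered study time points
#'
#' The canonical longitudinal design: normal chow (`T0`), two weeks of
#' acclimatization baseline on the purified diet with iron-supplemented water
#' (`B7`, `B14`), two weeks of low-iron (LI) challenge (`LI7`, `LI14`) and two
#' weeks of iron repletion (`R7`, `R14`).
#'
#' @export
TIMEPOINT_LEVELS <- c("T0", "B7", "B14", "LI7", "LI14", "R7", "R14")

#' Map time-point labels to dietary phases
#'
#' @param timepoints character vector of time-point labels.
#' @return factor with levels `pre_shift`, `baseline`, `low_iron`,
#'   `repletion`.
#' @export
timepoint_phase <- function(timepoints) {
  tp <- as.character(timepoints)
  phase <- ifelse(tp == "T0", "pre_shift",
           ifelse(grepl("^B", tp), "baseline",
           ifelse(grepl("^LI", tp), "low_iron",
           ifelse(grepl("^R", tp), "repletion", NA_character_))))
  if (anyNA(phase)) {
    stop("unrecognised time-point label(s): ",
         paste(unique(tp[is.na(phase)]), collapse = ", "))
  }
  factor(phase, levels = c("pre_shift", "baseline", "low_iron", "repletion"))
}

#' Construct an OTU count table
#'
#' The central community object: a samples x OTUs matrix of non-negative
#' integer read counts with unique sample and OTU identifiers. If the table
#' has been rarefied, `rarefied_depth` records the common depth and every row
#' must sum to it exactly.
#'
#' @param counts numeric matrix (samples x OTUs) of non-negative integers,
#'   with rownames (sample ids) and colnames (OTU ids).
#' @param rarefied_depth optional integer; the depth every sample was
#'   rarefied to.
#' @return an object of class `OTUTable` with elements `counts`,
#'   `sample_ids`, `otu_ids` and `rarefied_depth`.
#' @export
otu_table <- function(counts, rarefied_depth = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must carry sample ids (rownames) and OTU ids (colnames)")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in OTU table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids in OTU table")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integral")
  storage.mode(counts) <- "double"   # exact for counts < 2^53
  if (!is.null(rarefied_depth)) {
    rarefied_depth <- as.numeric(rarefied_depth)
    rs <- rowSums(counts)
    if (any(rs != rarefied_depth))
      stop("rarefied_depth set but row sums differ from it")
  }
  structure(
    list(counts = counts,
         sample_ids = if (is.null(rownames(counts))) character(0)
                      else rownames(counts),
         otu_ids = if (is.null(colnames(counts))) character(0)
                   else colnames(counts),
         rarefied_depth = rarefied_depth),
    class = "OTUTable")
}

#' @export
print.OTUTable <- function(x, ...) {
  cat(sprintf("OTUTable: %d samples x %d OTUs; %s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$rarefied_depth)) "not rarefied"
              else sprintf("rarefied to %d reads", as.integer(x$rarefied_depth))))
  invisible(x)
}

#' @export
dim.OTUTable <- function(x) dim(x$counts)

# coerce OTUTable-or-matrix input to a counts matrix
.counts <- function(table) {
  if (inherits(table, "OTUTable")) table$counts else as.matrix(table)
}

#' Subset an OTU table
#'
#' @param table an `OTUTable`.
#' @param samples,otus character or logical/integer index of rows / columns
#'   to keep; `NULL` keeps all.
#' @return an `OTUTable`. `rarefied_depth` is preserved only when no OTU
#'   columns are dropped (dropping columns breaks constant row sums).
#' @export
subset_table <- function(table, samples = NULL, otus = NULL) {
  stopifnot(inherits(table, "OTUTable"))
  m <- table$counts
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  if (!is.null(otus)) m <- m[, otus, drop = FALSE]
  depth <- if (is.null(otus) || identical(ncol(m), ncol(table$counts)))
    table$rarefied_depth else NULL
  otu_table(m, rarefied_depth = depth)
}

#' Relative abundances of an OTU table
#'
#' @param table `OTUTable` or counts matrix.
#' @return matrix of per-sample proportions (rows sum to 1).
#' @export
relative_abundance <- function(table) {
  m <- .counts(table)
  rs <- rowSums(m)
  if (any(rs == 0)) stop("sample(s) with zero total reads: ",
                         paste(rownames(m)[rs == 0], collapse = ", "))
  m / rs
}

#' Validate sample metadata
#'
#' Checks the per-sample record linking each sequenced sample to its mouse,
#' experimental group, cage, sex and time point, and orders the time-point
#' factor.
#'
#' @param df data.frame with columns `sample_id`, `mouse_id`, `group`,
#'   `cage`, `sex`, `timepoint`.
#' @param timepoint_levels ordered vector of admissible time-point labels.
#' @return the validated data.frame with `timepoint` an ordered factor;
#'   class `c("SampleMetadata", "data.frame")`.
#' @export
sample_metadata <- function(df, timepoint_levels = TIMEPOINT_LEVELS) {
  required <- c("sample_id", "mouse_id", "group", "cage", "sex", "timepoint")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$mouse_id <- as.character(df$mouse_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  tp <- as.character(df$timepoint)
  bad <- setdiff(unique(tp), timepoint_levels)
  if (length(bad))
    stop("unknown timepoint label(s): ", paste(bad, collapse = ", "))
  df$timepoint <- factor(tp, levels = timepoint_levels, ordered = TRUE)
  if (anyDuplicated(df[, c("mouse_id", "timepoint")]))
    stop("each (mouse_id, timepoint) may appear at most once")
  class(df) <- c("SampleMetadata", "data.frame")
  df
}
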