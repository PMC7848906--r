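# Post-clustering filtering and rarefaction. The fixed order is: removal of
# organellar / eukaryotic / domain-unclassified OTUs, then the dataset-wide
# rare-OTU filter, then rarefaction to a common depth. Filtering never alters
# surviving counts, only membership.

.UNCLASSIFIED <- c("", "unknown", "unclassified", "unknown_unclassified", NA)

#' Remove mitochondrial, chloroplast, eukaryotic and domain-unclassified OTUs
#'
#' Drops every OTU whose lineage is classified to mitochondria or
#' chloroplasts at any rank, whose domain is Eukaryota, or that is
#' unclassified at the domain level (including OTUs absent from the taxonomy
#' map, which are treated as domain-unclassified).
#'
#' @param table an `OTUTable`.
#' @param taxonomy data.frame as returned by [read_taxonomy()].
#' @return filtered `OTUTable` (possibly with zero OTUs).
#' @export
remove_unwanted_taxa <- function(table, taxonomy) {
  stopifnot(inherits(table, "OTUTable"))
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  idx <- match(table$otu_ids, taxonomy$otu_id)
  flagged <- vapply(seq_along(table$otu_ids), function(i) {
    j <- idx[i]
    if (is.na(j)) return(TRUE)                       # no taxonomy record
    lin <- tolower(unlist(taxonomy[j, ranks]))
    dom <- lin[1]
    if (is.na(dom) || dom %in% .UNCLASSIFIED) return(TRUE)
    if (dom == "eukaryota") return(TRUE)
    any(grepl("mitochondria|chloroplast", lin[!is.na(lin)]))
  }, logical(1))
  subset_table(table, otus = !flagged)
}

#' Remove dataset-wide rare OTUs
#'
#' Drops OTUs whose total read count across all samples is below
#' `min_total_reads`; totals exactly at the threshold are retained.
#'
#' @param table an `OTUTable`.
#' @param min_total_reads minimum dataset-wide total (default 100 reads).
#' @return filtered `OTUTable`.
#' @export
filter_rare_otus <- function(table, min_total_reads = 100) {
  stopifnot(inherits(table, "OTUTable"))
  keep <- colSums(table$counts) >= min_total_reads
  subset_table(table, otus = keep)
}

#' Rarefy an OTU table to a common depth
#'
#' Each sample's reads are subsampled uniformly without replacement (a single
#' multivariate-hypergeometric draw) to exactly `depth` reads. Samples with
#' fewer than `depth` total reads are dropped with a warning naming them.
#'
#' @param table an `OTUTable`.
#' @param depth target reads per sample (default 10000).
#' @param seed integer seed; a fixed seed gives an identical draw.
#' @return rarefied `OTUTable` with `rarefied_depth = depth`; attribute
#'   `dropped_samples` lists removed samples.
#' @export
rarefy <- function(table, depth = 10000, seed = 1L) {
  stopifnot(inherits(table, "OTUTable"), depth > 0)
  m <- table$counts
  totals <- rowSums(m)
  drop <- totals < depth
  if (all(drop))
    stop("all samples have fewer than ", depth, " reads; nothing to rarefy")
  if (any(drop))
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(rownames(m)[drop], collapse = ", "))
  m <- m[!drop, , drop = FALSE]
  set.seed(seed)
  out <- t(apply(m, 1, function(row) {
    if (sum(row) == depth) return(row)
    reads <- rep.int(seq_along(row), row)
    kept <- reads[sample.int(length(reads), depth)]
    tabulate(kept, nbins = length(row))
  }))
  dimnames(out) <- dimnames(m)
  res <- otu_table(out, rarefied_depth = depth)
  attr(res, "dropped_samples") <- rownames(table$counts)[drop]
  attr(res, "seed") <- seed
  res
}
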