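# Readers and writers for the mothur-style text formats the pipeline
# consumes: shared OTU tables, cons.taxonomy lineages, metadata TSV, plus a
# provenance sidecar.

#' Read a mothur shared-format OTU table
#'
#' The shared format is tab-separated with header
#' `label Group numOtus Otu...` and one row per sample (`Group`).
#'
#' @param path path to a shared file.
#' @return an [otu_table()].
#' @export
read_shared <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty shared file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 4 ||
      !identical(header[1:3], c("label", "Group", "numOtus")))
    stop("malformed shared header (expected 'label\\tGroup\\tnumOtus\\tOtu...'): line 1")
  otu_ids <- header[-(1:3)]
  n_otus <- length(otu_ids)
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != n_otus + 3L)
      stop(sprintf("shared line %d has %d fields, expected %d",
                   i, length(f), n_otus + 3L))
    declared <- suppressWarnings(as.integer(f[3]))
    if (is.na(declared) || declared != n_otus)
      stop(sprintf("shared line %d: numOtus=%s inconsistent with %d OTU columns",
                   i, f[3], n_otus))
    cnt <- suppressWarnings(as.numeric(f[-(1:3)]))
    if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
      stop(sprintf("shared line %d: non-integer or negative count", i))
    list(group = f[2], counts = cnt)
  })
  groups <- vapply(rows, `[[`, character(1), "group")
  if (anyDuplicated(groups)) {
    dup <- groups[duplicated(groups)][1]
    line <- which(groups == dup)[2] + 1L
    stop(sprintf("duplicate Group '%s' at shared line %d", dup, line))
  }
  m <- do.call(rbind, lapply(rows, `[[`, "counts"))
  dimnames(m) <- list(groups, otu_ids)
  otu_table(m)
}

#' Write an OTU table in mothur shared format
#'
#' @param table an `OTUTable`.
#' @param path output path.
#' @param label value for the `label` column (the clustering cutoff in
#'   mothur output; cosmetic here).
#' @export
write_shared <- function(table, path, label = "0.03") {
  m <- .counts(table)
  header <- paste(c("label", "Group", "numOtus", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(label, rownames(m)[i], ncol(m),
            format(m[i, ], scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read an OTU table as plain TSV (samples x OTUs)
#'
#' @param table an `OTUTable`.
#' @param path file path.
#' @return `read_counts_tsv` returns an [otu_table()].
#' @export
write_counts_tsv <- function(table, path) {
  m <- .counts(table)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") stop("first column must be sample_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  otu_table(m)
}

#' Read a mothur cons.taxonomy file
#'
#' Expects columns `OTU`, `Size`, `Taxonomy`, the lineage given as
#' `Rank(confidence);Rank(confidence);...`.
#'
#' @param path path to a cons.taxonomy TSV.
#' @return data.frame with columns `otu_id`, `domain` .. `genus` and
#'   matching `*_conf` confidence percentages (`NA` where unassigned).
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("otu", "taxonomy") %in% names(df)))
    stop("cons.taxonomy file must have OTU and Taxonomy columns")
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  parsed <- lapply(df$taxonomy, function(s) {
    parts <- strsplit(sub(";$", "", s), ";", fixed = TRUE)[[1]]
    name <- sub("\\(\\d+\\)$", "", parts)
    conf <- suppressWarnings(as.numeric(sub(".*\\((\\d+)\\)$", "\\1", parts)))
    length(name) <- length(ranks); length(conf) <- length(ranks)
    list(name = name, conf = conf)
  })
  out <- data.frame(otu_id = df$otu, stringsAsFactors = FALSE)
  for (r in seq_along(ranks)) {
    out[[ranks[r]]] <- vapply(parsed, function(p) p$name[r], character(1))
    out[[paste0(ranks[r], "_conf")]] <-
      vapply(parsed, function(p) p$conf[r], numeric(1))
  }
  out
}

#' Read a sample metadata TSV
#'
#' @param path TSV with columns `sample_id`, `mouse_id`, `group`, `cage`,
#'   `sex`, `timepoint`.
#' @return a [sample_metadata()] data.frame.
#' @export
read_metadata <- function(path) {
  sample_metadata(read.delim(path, stringsAsFactors = FALSE))
}

#' Write a provenance sidecar
#'
#' Records the parameters, seeds and dropped samples/OTUs of a processing
#' step next to its output so downstream analyses are reproducible.
#'
#' @param path output JSON path.
#' @param ... named fields to record.
#' @export
write_provenance <- function(path, ...) {
  info <- list(package = "ferromic",
               version = as.character(utils::packageVersion("ferromic")),
               ...)
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
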