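# End-to-end orchestration: filter -> rarefy -> diversity -> paired stats
# -> NMDS/PERMANOVA per transition -> the four selections -> pseudo-F
# benchmark -> sensitivity classification, with every artifact and a
# provenance manifest written to an output directory.

#' Assemble a pipeline configuration
#'
#' Either `simulation` (arguments for [sim_config()]) or `inputs` (paths:
#' `shared` or `counts_tsv`, `metadata`, optional `taxonomy`) must be given.
#'
#' @param simulation named list of [sim_config()] arguments, or `NULL`.
#' @param inputs named list of input paths, or `NULL`.
#' @param out_dir output directory.
#' @param min_total_reads dataset-wide rare-OTU threshold (default 100).
#' @param rarefy_depth rarefaction depth (default 10000).
#' @param transitions list of 2-vectors of time points to analyse (default
#'   the three major treatment transitions).
#' @param selection named list of per-technique argument lists
#'   (`rf`, `indval`, `presence`, `ttest`).
#' @param classification named list of [classify_sensitivity()] threshold
#'   arguments.
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param seed master seed.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(simulation = list(), inputs = NULL,
                            out_dir = tempfile("ferromic_run_"),
                            min_total_reads = 100, rarefy_depth = 10000,
                            transitions = list(c("T0", "B7"),
                                               c("B14", "LI7"),
                                               c("LI14", "R7")),
                            selection = list(),
                            classification = list(),
                            n_permutations = 999, seed = 1L) {
  if (is.null(simulation) && is.null(inputs))
    stop("config needs a simulation block or input paths")
  structure(list(simulation = simulation, inputs = inputs, out_dir = out_dir,
                 min_total_reads = min_total_reads,
                 rarefy_depth = rarefy_depth, transitions = transitions,
                 selection = selection, classification = classification,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()] (or a list coercible to one).
#' @return invisibly, a list with all intermediate and final objects:
#'   `table` (rarefied), `metadata`, `truth` (simulation only), `diversity`,
#'   `paired_tests`, `permanova` and `ordination` per transition,
#'   `selections`, `evaluations`, `comparison` (when >= 2 groups),
#'   `sensitivity`, `manifest`. All artifacts are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "PipelineConfig")) config <- do.call(pipeline_config, config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL

  if (!is.null(config$simulation)) {
    cohort <- .stage("simulate", {
      args <- config$simulation
      if (is.null(args$seed)) args$seed <- config$seed
      generate_cohort(do.call(sim_config, args))
    })
    table <- cohort$table; metadata <- cohort$metadata; truth <- cohort$truth
    write_cohort(cohort, file.path(out, "simulated"))
  } else {
    table <- .stage("read_inputs", {
      if (!is.null(config$inputs$shared)) read_shared(config$inputs$shared)
      else read_counts_tsv(config$inputs$counts_tsv)
    })
    metadata <- .stage("read_metadata", read_metadata(config$inputs$metadata))
    if (!is.null(config$inputs$taxonomy))
      table <- .stage("remove_unwanted_taxa",
                      remove_unwanted_taxa(table,
                                           read_taxonomy(config$inputs$taxonomy)))
  }

  table <- .stage("filter_rare_otus",
                  filter_rare_otus(table, config$min_total_reads))
  dropped <- character(0)
  table <- .stage("rarefy", {
    r <- withCallingHandlers(
      rarefy(table, depth = config$rarefy_depth,
             seed = .derive_seed(config$seed, 1)),
      warning = function(w) invokeRestart("muffleWarning"))
    dropped <- attr(r, "dropped_samples")
    r
  })
  metadata <- metadata[metadata$sample_id %in% table$sample_ids, ,
                       drop = FALSE]
  write_shared(table, file.path(out, "rarefied.shared"))

  div <- .stage("diversity", diversity_table(table))
  write.table(div, file.path(out, "diversity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  paired <- .stage("paired_stats", {
    v <- div$inverse_simpson[match(metadata$sample_id, div$sample_id)]
    sequential_paired_tests(v, metadata)
  })
  write.table(paired, file.path(out, "paired_tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  perm <- list(); ords <- list()
  for (tr in config$transitions) {
    key <- paste(tr, collapse = "->")
    ts <- .stage(paste0("transition ", key),
                 transition_subset(table, metadata, tr[1], tr[2]))
    dm <- distance_matrix(ts$table)
    perm[[key]] <- .stage(paste0("permanova ", key),
      permanova(dm, ts$labels, n_permutations = config$n_permutations,
                seed = .derive_seed(config$seed, 2)))
    ords[[key]] <- .stage(paste0("nmds ", key),
      nmds(dm, seed = .derive_seed(config$seed, 3)))
    write_ordination(ords[[key]],
                     file.path(out, paste0("nmds_", gsub("->", "_", key),
                                           ".tsv")))
  }

  methods <- c("rf", "indval", "presence", "ttest")
  sel_args <- list(
    rf = c(list(seed = .derive_seed(config$seed, 4)), config$selection$rf),
    indval = c(list(seed = .derive_seed(config$seed, 5)),
               config$selection$indval),
    presence = config$selection$presence,
    ttest = c(list(correction = "bonferroni"), config$selection$ttest))
  selections <- list(); evaluations <- list()
  for (tr in config$transitions) {
    key <- paste(tr, collapse = "->")
    for (mth in methods) {
      tag <- paste(mth, key, sep = "|")
      selections[[tag]] <- .stage(paste0("select ", tag),
        do.call(select_otus, c(list(table = table, metadata = metadata,
                                    from = tr[1], to = tr[2], method = mth),
                               sel_args[[mth]])))
      evaluations[[tag]] <- .stage(paste0("evaluate ", tag),
        evaluate_selection(table, metadata, tr, selections[[tag]],
                           n_permutations = config$n_permutations,
                           seed = .derive_seed(config$seed, 6)))
    }
  }
  eval_df <- evaluation_table(evaluations)
  write.table(eval_df, file.path(out, "evaluation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  comparison <- if (length(config$transitions) >= 2)
    .stage("compare_techniques",
           suppressWarnings(compare_techniques(evaluations))) else NULL
  if (!is.null(comparison))
    jsonlite::write_json(comparison[c("summary", "pairwise")],
                         file.path(out, "technique_comparison.json"),
                         digits = NA, pretty = TRUE, dataframe = "rows")

  sens <- .stage("classify_sensitivity",
    do.call(classify_sensitivity,
            c(list(table = table, metadata = metadata),
              config$classification)))
  write.table(sens, file.path(out, "sensitivity_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = config$seed, rarefy_depth = config$rarefy_depth,
    min_total_reads = config$min_total_reads,
    n_permutations = config$n_permutations,
    transitions = vapply(config$transitions, paste, character(1),
                         collapse = "->"),
    dropped_samples = dropped,
    n_samples = nrow(table$counts), n_otus = ncol(table$counts),
    classification = config$classification)
  write_provenance(file.path(out, "manifest.json"), manifest = manifest)

  invisible(list(table = table, metadata = metadata, truth = truth,
                 diversity = div, paired_tests = paired, permanova = perm,
                 ordination = ords, selections = selections,
                 evaluations = evaluations, comparison = comparison,
                 sensitivity = sens, manifest = manifest))
}
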