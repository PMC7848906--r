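# Dirichlet-multinomial cohort simulator. Generates the longitudinal
# structure the analysis assumes — a log-normal baseline community with
# mouse and cage random effects, a global diet-shift perturbation from the
# first post-T0 time point onward, planted iron-sensitive OTUs suppressed
# during the low-iron phase (a subset recovering under repletion) — plus the
# ground truth those plants define.

#' Simulation configuration
#'
#' Defaults encode the study design being emulated: a 310-OTU community, two
#' cages of five mice forming one experimental group, seven time points
#' (normal chow, two baseline weeks on the purified diet, two weeks of
#' low-iron challenge, two weeks of repletion), six iron-sensitive OTUs of
#' which three recover. `sensitivity_logfc = -20` (natural log) drives
#' sensitive OTUs far below the 1-in-10,000 detection limit during the LI
#' phase, emulating complete loss.
#'
#' @param n_otus number of OTUs.
#' @param n_mice number of mice (split evenly over cages).
#' @param n_cages number of cages; cage effects are shared by cage mates.
#' @param timepoints ordered subset of [TIMEPOINT_LEVELS].
#' @param library_size_mean,library_size_dispersion negative-binomial mean
#'   and dispersion of per-sample read totals (dispersion 0 = constant).
#' @param base_abundance_logmean,base_abundance_logsd log-normal baseline
#'   species-abundance distribution (natural log).
#' @param diet_shift_fraction fraction of OTUs perturbed by the chow ->
#'   purified-diet switch (applied from the first post-T0 time point on).
#' @param diet_shift_logfc_sd sd of the diet-shift log-fold-changes.
#' @param n_sensitive,n_recovering planted iron-sensitive OTUs and the
#'   subset that recovers under repletion (`n_recovering <= n_sensitive`).
#' @param sensitivity_logfc log-fold-change applied to sensitive OTUs at LI
#'   time points (and at repletion time points for non-recovering OTUs).
#' @param mouse_effect_sd,cage_effect_sd sd of per-OTU mouse and cage random
#'   effects on the log scale.
#' @param overdispersion Dirichlet concentration scale; larger = closer to
#'   multinomial sampling (`Inf` = exactly multinomial).
#' @param group_label experimental-group id recorded in the metadata.
#' @param seed master seed; all randomness derives from it.
#' @return validated list of class `SimulationConfig`.
#' @export
sim_config <- function(n_otus = 310, n_mice = 10, n_cages = 2,
                       timepoints = TIMEPOINT_LEVELS,
                       library_size_mean = 20000,
                       library_size_dispersion = 0.05,
                       base_abundance_logmean = 0,
                       base_abundance_logsd = 2,
                       diet_shift_fraction = 0.3,
                       diet_shift_logfc_sd = 1,
                       n_sensitive = 6, n_recovering = 3,
                       sensitivity_logfc = -20,
                       mouse_effect_sd = 0.3, cage_effect_sd = 0.2,
                       overdispersion = 500,
                       group_label = "G1", seed = 1L) {
  cfg <- list(n_otus = n_otus, n_mice = n_mice, n_cages = n_cages,
              timepoints = as.character(timepoints),
              library_size_mean = library_size_mean,
              library_size_dispersion = library_size_dispersion,
              base_abundance_logmean = base_abundance_logmean,
              base_abundance_logsd = base_abundance_logsd,
              diet_shift_fraction = diet_shift_fraction,
              diet_shift_logfc_sd = diet_shift_logfc_sd,
              n_sensitive = n_sensitive, n_recovering = n_recovering,
              sensitivity_logfc = sensitivity_logfc,
              mouse_effect_sd = mouse_effect_sd,
              cage_effect_sd = cage_effect_sd,
              overdispersion = overdispersion,
              group_label = group_label, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_otus >= 1, n_mice >= 1, n_cages >= 1, n_mice >= n_cages)
    if (!(n_recovering <= n_sensitive && n_sensitive <= n_otus))
      stop("need n_recovering <= n_sensitive <= n_otus")
    if (length(timepoints) == 0 || anyDuplicated(timepoints))
      stop("timepoints must be non-empty and unique")
    sds <- c(library_size_dispersion, base_abundance_logsd,
             diet_shift_logfc_sd, mouse_effect_sd, cage_effect_sd)
    if (any(sds < 0)) stop("sd/dispersion parameters must be >= 0")
    if (overdispersion <= 0) stop("overdispersion must be > 0 (Inf allowed)")
    if (diet_shift_fraction < 0 || diet_shift_fraction > 1)
      stop("diet_shift_fraction must be in [0, 1]")
  })
  timepoint_phase(cfg$timepoints)  # validates labels
  structure(cfg, class = "SimulationConfig")
}

# deterministic sub-seed derivation (kept below 2^31)
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103 + offset * 12289) %% 2147483647)
}

.softmax <- function(logx) {
  e <- exp(logx - max(logx))
  e / sum(e)
}

# one Dirichlet-multinomial draw: n reads around composition p with
# concentration theta (Inf = multinomial)
.rdirmult <- function(n, p, theta) {
  q <- if (is.finite(theta)) {
    w <- rgamma(length(p), shape = theta * p, rate = 1)
    if (sum(w) <= 0) p else w / sum(w)
  } else p
  as.numeric(stats::rmultinom(1, size = n, prob = q))
}

#' Generate a longitudinal cohort with ground truth
#'
#' One sample per mouse per time point. Counts are Dirichlet-multinomial
#' around per-mouse expected compositions built on the log scale from the
#' baseline abundances, mouse and cage random effects, the diet-shift
#' log-fold-changes (first post-T0 time point onward), and
#' `sensitivity_logfc` applied to sensitive OTUs at LI time points and —
#' for non-recovering OTUs only — still at repletion time points.
#'
#' Sensitive OTUs are planted among OTUs whose expected post-shift relative
#' abundance is appreciable (>= 0.5%, a clear margin above the 0.1%
#' "appreciable" classification floor), mirroring the observation the
#' classifier targets: taxa present at appreciable baseline levels that fall
#' below the detection limit under iron limitation.
#'
#' @param config a [sim_config()].
#' @return list of class `Cohort`: `table` ([otu_table()]), `metadata`
#'   ([sample_metadata()]), `truth` (`GroundTruth`: `sensitive_otus`,
#'   `recovering_otus`, `diet_shift_otus`, `logfc` per OTU per phase).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  phases <- timepoint_phase(config$timepoints)
  if (config$n_sensitive > 0 && !any(phases == "low_iron"))
    stop("config plants sensitive OTUs but has no LI time point")
  set.seed(config$seed)
  n_otus <- config$n_otus
  otu_ids <- sprintf("Otu%04d", seq_len(n_otus))

  b <- rnorm(n_otus, config$base_abundance_logmean, config$base_abundance_logsd)

  n_shift <- round(config$diet_shift_fraction * n_otus)
  diet_idx <- if (n_shift > 0) sort(sample.int(n_otus, n_shift)) else integer(0)
  d <- numeric(n_otus)
  if (n_shift > 0) d[diet_idx] <- rnorm(n_shift, 0, config$diet_shift_logfc_sd)

  # plant sensitive OTUs among appreciably abundant post-shift OTUs
  p_shift <- .softmax(b + d)
  eligible <- setdiff(which(p_shift >= 0.005), diet_idx)
  sens_idx <- integer(0)
  if (config$n_sensitive > 0) {
    if (length(eligible) >= config$n_sensitive) {
      sens_idx <- sort(sample(eligible, config$n_sensitive))
    } else {
      pool <- setdiff(order(p_shift, decreasing = TRUE), diet_idx)
      sens_idx <- sort(pool[seq_len(config$n_sensitive)])
    }
  }
  rec_idx <- if (config$n_recovering > 0)
    sort(sample(sens_idx, config$n_recovering)) else integer(0)

  mice <- sprintf("M%02d", seq_len(config$n_mice))
  cage_of <- rep(seq_len(config$n_cages), length.out = config$n_mice)
  cage_of <- sort(cage_of)
  sex_of_cage <- rep(c("F", "M"), length.out = config$n_cages)

  cage_eff <- matrix(rnorm(config$n_cages * n_otus, 0, config$cage_effect_sd),
                     nrow = config$n_cages)
  mouse_eff <- matrix(rnorm(config$n_mice * n_otus, 0, config$mouse_effect_sd),
                      nrow = config$n_mice)

  n_samples <- config$n_mice * length(config$timepoints)
  lib_sizes <- if (config$library_size_dispersion == 0)
    rep(round(config$library_size_mean), n_samples)
  else
    pmax(1L, rnbinom(n_samples, mu = config$library_size_mean,
                     size = 1 / config$library_size_dispersion))

  s <- numeric(n_otus); s[sens_idx] <- config$sensitivity_logfc
  s_norec <- numeric(n_otus)
  s_norec[setdiff(sens_idx, rec_idx)] <- config$sensitivity_logfc

  counts <- matrix(0, nrow = n_samples, ncol = n_otus)
  meta <- vector("list", n_samples)
  k <- 0L
  for (tp_i in seq_along(config$timepoints)) {
    tp <- config$timepoints[tp_i]
    ph <- as.character(phases[tp_i])
    t_eff <- switch(ph,
                    pre_shift = numeric(n_otus),
                    baseline = d,
                    low_iron = d + s,
                    repletion = d + s_norec)
    for (j in seq_len(config$n_mice)) {
      k <- k + 1L
      logx <- b + t_eff + cage_eff[cage_of[j], ] + mouse_eff[j, ]
      counts[k, ] <- .rdirmult(lib_sizes[k], .softmax(logx),
                               config$overdispersion)
      meta[[k]] <- data.frame(
        sample_id = paste0(mice[j], "_", tp), mouse_id = mice[j],
        group = config$group_label, cage = paste0("C", cage_of[j]),
        sex = sex_of_cage[cage_of[j]], timepoint = tp,
        stringsAsFactors = FALSE)
    }
  }
  metadata <- sample_metadata(do.call(rbind, meta))
  rownames(counts) <- metadata$sample_id
  colnames(counts) <- otu_ids

  logfc <- data.frame(
    otu_id = otu_ids,
    diet_shift = d,
    low_iron = s,
    repletion = s_norec,
    stringsAsFactors = FALSE)
  truth <- structure(
    list(sensitive_otus = otu_ids[sens_idx],
         recovering_otus = otu_ids[rec_idx],
         diet_shift_otus = otu_ids[diet_idx],
         logfc = logfc),
    class = "GroundTruth")
  structure(list(table = otu_table(counts), metadata = metadata,
                 truth = truth, config = config),
            class = "Cohort")
}

#' @export
print.Cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated cohort: %d mice x %d time points, %d OTUs (%d sensitive, %d recovering)\n",
    x$config$n_mice, length(x$config$timepoints), x$config$n_otus,
    length(x$truth$sensitive_otus), length(x$truth$recovering_otus)))
  invisible(x)
}

#' Default per-phase stool-iron levels (log10 scale)
#'
#' Baseline and repletion high, the low-iron phase about one order of
#' magnitude lower — the qualitative pattern of total stool iron across the
#' feeding protocol.
#'
#' @export
default_iron_phase_means <- function() {
  data.frame(
    phase = c("pre_shift", "baseline", "low_iron", "repletion"),
    mean_log10 = c(2.3, 2.3, 1.3, 2.3),
    sd_log10 = 0.2,
    stringsAsFactors = FALSE)
}

#' Generate per-sample iron measurements
#'
#' Log-normal stool (or serum) iron with phase-specific means: high at
#' baseline, low during LI challenge, restored under repletion.
#'
#' @param metadata a [sample_metadata()].
#' @param phase_means data.frame with columns `phase`, `mean_log10`,
#'   `sd_log10`; see [default_iron_phase_means()].
#' @param seed integer seed.
#' @return data.frame: `sample_id`, `mouse_id`, `timepoint`, `phase`,
#'   `iron` (linear scale).
#' @export
generate_iron_measurements <- function(metadata,
                                       phase_means = default_iron_phase_means(),
                                       seed = 1L) {
  if (!nrow(metadata)) stop("metadata is empty")
  if (any(phase_means$sd_log10 < 0)) stop("sd_log10 must be >= 0")
  ph <- as.character(timepoint_phase(metadata$timepoint))
  i <- match(ph, phase_means$phase)
  if (anyNA(i)) stop("phase_means missing phase(s): ",
                     paste(unique(ph[is.na(i)]), collapse = ", "))
  set.seed(seed)
  logv <- rnorm(nrow(metadata), phase_means$mean_log10[i],
                phase_means$sd_log10[i])
  data.frame(sample_id = metadata$sample_id, mouse_id = metadata$mouse_id,
             timepoint = as.character(metadata$timepoint), phase = ph,
             iron = 10^logv, stringsAsFactors = FALSE)
}

#' Generate qPCR Ct records with known fold changes
#'
#' Builds per-animal target and reference Ct values such that the
#' comparative threshold-cycle estimator is unbiased for the configured fold
#' change: the treatment arm's target Ct is shifted by `-log2(fold_change)`
#' relative to control, with independent Gaussian noise on every reading.
#'
#' @param n_per_arm animals per arm.
#' @param true_fold_changes named positive numeric vector (one fold change
#'   per target gene).
#' @param noise_sd Gaussian noise sd on each Ct reading (cycles).
#' @param seed integer seed.
#' @param tissue tissue label.
#' @param reference_gene name of the reference gene.
#' @return data.frame with columns `animal`, `tissue`, `gene`, `ct`, `role`,
#'   `arm`, suitable for [ddct_fold_change()].
#' @export
generate_ct_records <- function(n_per_arm, true_fold_changes, noise_sd = 0.2,
                                seed = 1L, tissue = "duodenum",
                                reference_gene = "Actb") {
  if (any(true_fold_changes <= 0)) stop("fold changes must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(names(true_fold_changes)))
    names(true_fold_changes) <- paste0("gene", seq_along(true_fold_changes))
  set.seed(seed)
  base_ref <- 18; base_target <- 22
  rows <- list()
  for (arm in c("treatment", "control")) {
    for (a in seq_len(n_per_arm)) {
      animal <- paste0(substr(arm, 1, 1), a)
      rows[[length(rows) + 1]] <- data.frame(
        animal = animal, tissue = tissue, gene = reference_gene,
        ct = base_ref + rnorm(1, 0, noise_sd), role = "reference", arm = arm,
        stringsAsFactors = FALSE)
      for (g in names(true_fold_changes)) {
        shift <- if (arm == "treatment") -log2(true_fold_changes[[g]]) else 0
        rows[[length(rows) + 1]] <- data.frame(
          animal = animal, tissue = tissue, gene = g,
          ct = base_target + shift + rnorm(1, 0, noise_sd), role = "target",
          arm = arm, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a simulated cohort to disk
#'
#' Emits the OTU table in mothur shared format and plain TSV, the metadata
#' TSV, and the ground truth as JSON.
#'
#' @param cohort a `Cohort` from [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(out_dir, c("cohort.shared", "cohort_counts.tsv",
                            "metadata.tsv", "ground_truth.json"))
  write_shared(cohort$table, f[1])
  write_counts_tsv(cohort$table, f[2])
  write.table(as.data.frame(cohort$metadata), f[3], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(sensitive_otus = cohort$truth$sensitive_otus,
         recovering_otus = cohort$truth$recovering_otus,
         diet_shift_otus = cohort$truth$diet_shift_otus,
         logfc = cohort$truth$logfc),
    f[4], digits = NA, pretty = TRUE)
  invisible(f)
}
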