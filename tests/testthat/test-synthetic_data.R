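test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "SimulationConfig")
  expect_error(sim_config(n_sensitive = 5, n_recovering = 6),
               "n_recovering <= n_sensitive")
  expect_error(sim_config(n_otus = 4, n_sensitive = 5), "n_sensitive")
  expect_error(sim_config(mouse_effect_sd = -1), ">= 0")
  expect_error(sim_config(timepoints = c("B7", "B7")), "unique")
  expect_error(sim_config(timepoints = c("B7", "X9")), "unrecognised")
  # sensitive OTUs need an LI time point
  cfg <- sim_config(timepoints = c("T0", "B7", "B14"), n_sensitive = 2,
                    n_recovering = 0)
  expect_error(generate_cohort(cfg), "no LI time point")
})

test_that("generate_cohort structure, determinism and ground-truth invariants", {
  cfg <- sim_config(n_otus = 60, n_mice = 4, seed = 9)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$table$counts), 4 * 7)   # one sample per mouse per tp
  expect_equal(ncol(co$table$counts), 60)
  expect_true(all(co$truth$recovering_otus %in% co$truth$sensitive_otus))
  expect_length(intersect(co$truth$sensitive_otus,
                          co$truth$diet_shift_otus), 0)
  expect_length(co$truth$sensitive_otus, 6)
  expect_length(co$truth$recovering_otus, 3)
  # identical seed => identical output
  co2 <- generate_cohort(cfg)
  expect_identical(co$table$counts, co2$table$counts)
  expect_identical(co$truth, co2$truth)
  # fixed library size: row sums match the drawn (constant) library sizes
  cfg0 <- sim_config(n_otus = 30, n_mice = 3,
                     library_size_dispersion = 0,
                     library_size_mean = 5000, seed = 2)
  co0 <- generate_cohort(cfg0)
  expect_true(all(rowSums(co0$table$counts) == 5000))
})

test_that("null config gives exchangeable samples (binomial-CI check)", {
  cfg <- sim_config(n_otus = 50, n_mice = 5, n_cages = 1,
                    diet_shift_fraction = 0, n_sensitive = 0,
                    n_recovering = 0, mouse_effect_sd = 0,
                    cage_effect_sd = 0, overdispersion = Inf,
                    library_size_mean = 10000,
                    library_size_dispersion = 0, seed = 3)
  co <- generate_cohort(cfg)
  m <- co$table$counts
  tp <- as.character(co$metadata$timepoint)
  pooled <- colSums(m) / sum(m)
  for (t in unique(tp)) {
    rows <- tp == t
    n_t <- sum(m[rows, ])
    p_t <- colSums(m[rows, , drop = FALSE]) / n_t
    se <- sqrt(pmax(pooled * (1 - pooled), 1e-12) / n_t)
    z <- (p_t - pooled) / se
    expect_lt(max(abs(z)), 5)   # ~350 null z-scores; 5 sd bound
  }
})

test_that("strong suppression drives sensitive OTUs below detection at LI", {
  cfg <- sim_config(n_otus = 120, n_mice = 10,
                    library_size_mean = 10000,
                    library_size_dispersion = 0,
                    sensitivity_logfc = -20, seed = 4)
  co <- generate_cohort(cfg)
  li_rows <- co$metadata$timepoint %in% c("LI7", "LI14")
  sens <- co$table$counts[li_rows, co$truth$sensitive_otus, drop = FALSE]
  expect_true(all(sens == 0))
  # parameter-recovery invariant: undetectable in > 50% of mice at LI
  li_md <- co$metadata[li_rows, ]
  for (otu in co$truth$sensitive_otus) {
    undet <- vapply(unique(li_md$mouse_id), function(mm) {
      all(co$table$counts[li_md$sample_id[li_md$mouse_id == mm], otu] == 0)
    }, logical(1))
    expect_gt(mean(undet), 0.5)
  }
})

test_that("Monte-Carlo oracle: realized LI log-fold-change matches the target", {
  # measured against unaffected OTUs so compositional renormalization
  # cancels exactly: log(p_i/p_u) shifts by sensitivity_logfc at LI
  target <- -1.5
  reps <- 50
  est <- vapply(seq_len(reps), function(s) {
    co <- generate_cohort(sim_config(n_otus = 300, n_mice = 10,
                                     sensitivity_logfc = target, seed = s))
    m <- co$table$counts
    tp <- as.character(co$metadata$timepoint)
    b <- tp %in% c("B7", "B14"); li <- tp %in% c("LI7", "LI14")
    sens <- co$truth$sensitive_otus
    unaff <- setdiff(colnames(m), union(sens, co$truth$diet_shift_otus))
    ref <- log(sum(m[li, unaff]) / sum(m[b, unaff]))
    mean(vapply(sens, function(o)
      log(sum(m[li, o]) / sum(m[b, o])) - ref, numeric(1)))
  }, numeric(1))
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - target), 2 * mc_se + 0.02)
})

test_that("iron measurements: exactness at sd 0, determinism, and power", {
  md <- fix_metadata(mice = paste0("M", 1:10),
                     timepoints = c("B14", "LI14"))
  pm <- data.frame(phase = c("baseline", "low_iron"),
                   mean_log10 = c(2.3, 1.3), sd_log10 = 0)
  iron <- generate_iron_measurements(md, pm, seed = 1)
  expect_equal(sort(unique(iron$iron)), sort(10^c(1.3, 2.3)))

  pm$sd_log10 <- 0.2
  i1 <- generate_iron_measurements(md, pm, seed = 6)
  i2 <- generate_iron_measurements(md, pm, seed = 6)
  expect_identical(i1, i2)

  pm_bad <- pm; pm_bad$sd_log10 <- -0.1
  expect_error(generate_iron_measurements(md, pm_bad, seed = 1), ">= 0")
  expect_error(generate_iron_measurements(md[0, ], pm, seed = 1), "empty")

  # paired Wilcoxon detects a 1-log10 drop (n = 10, sd 0.2) with power > 0.9
  reps <- 200
  rejected <- vapply(seq_len(reps), function(s) {
    ir <- generate_iron_measurements(md, pm, seed = s)
    b <- ir[ir$timepoint == "B14", ]
    l <- ir[ir$timepoint == "LI14", ]
    v <- paired_wilcoxon(log10(b$iron[match(md$mouse_id[1:10], b$mouse_id)]),
                         log10(l$iron[match(md$mouse_id[1:10], l$mouse_id)]))
    v$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejected), 0.9)
})

test_that("Ct simulator is unbiased for the configured fold change", {
  expect_error(generate_ct_records(3, c(g = -1)), "> 0")
  reps <- 500
  fc <- vapply(seq_len(reps), function(s) {
    ct <- generate_ct_records(5, c(g = 2), noise_sd = 0.1, seed = s)
    ddct_fold_change(ct, "g", "duodenum")$fold_change
  }, numeric(1))
  expect_lt(abs(mean(fc) - 2) / 2, 0.05)
})

test_that("write_cohort emits readable artifacts", {
  co <- generate_cohort(sim_config(n_otus = 25, n_mice = 2, seed = 8))
  dir <- tempfile("cohort")
  files <- write_cohort(co, dir)
  expect_true(all(file.exists(files)))
  back <- read_shared(files[1])
  expect_identical(back$counts, co$table$counts)
  gt <- jsonlite::read_json(files[4], simplifyVector = TRUE)
  expect_identical(sort(gt$sensitive_otus), sort(co$truth$sensitive_otus))
})
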