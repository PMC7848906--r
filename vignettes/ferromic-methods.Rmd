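---
title: "ferromic: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ferromic: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ferromic` analyses longitudinal mouse gut-microbiome OTU tables from
dietary low-iron (LI) challenge designs: acclimatization baseline on a
purified diet (`B7`, `B14`) after normal chow (`T0`), two weeks of LI
challenge (`LI7`, `LI14`), and optional iron repletion (`R7`, `R14`). This
vignette records the statistical models, the conventions behind every
tunable parameter, what the synthetic-cohort generator does and does not
emulate, and the design choices made where the design was genuinely open.

## 1. Normalization pipeline

Processing order is fixed: **taxon removal → rare-OTU filter →
rarefaction**.

* *Taxon removal*: OTUs classified to mitochondria or chloroplasts at any
  rank, classified to Eukaryota, or unclassified at the domain level
  (including OTUs absent from the taxonomy map) are dropped.
* *Rare-OTU filter*: OTUs with fewer than `min_total_reads = 100` reads in
  the entire data set are dropped; totals exactly at the threshold are
  kept (the rule is a strict `<`).
* *Rarefaction*: each sample is subsampled **once**, uniformly without
  replacement (a multivariate-hypergeometric draw), to exactly
  `depth = 10000` reads. Rarefaction is a single seeded draw, not an
  average over draws, so all downstream analyses are reproducible from the
  recorded seed. Samples with fewer than `depth` reads are dropped with a
  warning naming them (scaling them up would fabricate reads; the seed and
  the dropped-sample list go into the provenance sidecar). The **detection
  limit** after rarefaction is one read, i.e. relative abundance 1e-4 at
  the default depth; "undetectable" always means zero reads.

Filtering operations never alter surviving counts, only membership.

## 2. Diversity

* Inverse Simpson `1/Σpᵢ²` with plug-in proportions `pᵢ = nᵢ/N` — the
  effective number of equally abundant taxa. The unbiased finite-sample
  variant (`N(N−1)/Σnᵢ(nᵢ−1)`) is available via `unbiased = TRUE`; the
  plug-in form is the default because it is the conventional index.
* Richness: number of OTUs with ≥ 1 read.
* Bray-Curtis `Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ)`, bounded in [0, 1]. On rarefied tables
  (equal row sums) counts and proportions give identical values.
* Summation is always in ascending OTU index so results are
  bit-reproducible.

## 3. PERMANOVA and NMDS

One-factor PERMANOVA partitions squared dissimilarities:
`SS_T = (1/N) Σ_{i<j} d²ᵢⱼ`, `SS_W = Σ_g (1/n_g) Σ_{i<j∈g} d²ᵢⱼ`,
`SS_B = SS_T − SS_W`, and `F = (SS_B/(a−1)) / (SS_W/(N−a))`.

* The permutation test shuffles sample labels **freely** — no
  stratification by mouse or cage — matching the conventional usage on
  repeated-measures microbiome data; a `strata` argument restores
  within-block permutation for users who want it.
* p-values use the add-one convention `(#{F* ≥ F} + 1)/(B + 1)`; ties
  (`F* = F`) count as exceedances, compared with a 1e-12 absolute
  tolerance so floating-point noise cannot break a tie the wrong way.
* `method = "exact"` enumerates all label permutations (N ≤ 9) and reports
  `#{F* ≥ F}/#perms` with the identity included.
* If `SS_W = 0` the statistic is reported as `+Inf` and the permutation
  p-value is still well defined.
* Only the one-factor design is provided; the studies this package targets
  test single transitions.

NMDS minimizes Kruskal stress-1
`sqrt(Σ(d̂ᵢⱼ − d*ᵢⱼ)² / Σ d̂ᵢⱼ²)` where `d*` is the isotonic regression of
the configuration distances on the input dissimilarities. The iterative
engine is `vegan::monoMDS` (global model, weak ties) — the same engine the
field's standard workflow uses — wrapped in an in-package multi-start
driver: one principal-coordinates start plus `n_starts − 1 = 19` random
configurations, keeping the lowest-stress solution (`max_iter = 300`,
stress threshold `tol = 1e-6`). Coordinates are centred; they are defined
only up to rotation/reflection, so tests compare stress and inter-point
distances, never raw coordinates. Degenerate inputs (all dissimilarities
equal) return a flagged non-converged result rather than an error.

## 4. Longitudinal statistics

* "Paired (nonparametric) Wilcoxon rank sum" in this literature denotes
  the **Wilcoxon signed-rank test** on within-subject differences — the
  standard paired Wilcoxon; that reading is used here. Zero differences
  are dropped; the exact sign-enumeration null is used for n ≤ 25 without
  ties among |differences|, otherwise a normal approximation with
  continuity correction and tie-corrected variance.
* Benjamini-Hochberg is applied within each family of sequential
  time-point comparisons per measurement (the figure-legend convention);
  the family is whatever vector the caller passes, so other groupings are
  possible.
* Two-sample t tests default to Welch: equal variances are not assumed
  because nothing in the design guarantees them.
* Comparative Ct: per animal `ΔCt = Ct_target − Ct_reference`,
  `ΔΔCt = mean ΔCt(treatment) − mean ΔCt(control)`, fold change
  `2^(−ΔΔCt)`, with a t test on per-animal ΔCt values reported alongside.

## 5. OTU-selection techniques

All four techniques receive **relative abundances** (the rarefied depth is
constant, so proportions lose nothing). Whether to transform abundances
was an open design point; the choices are:

* **Random forest** — rank-based, so transforms are irrelevant. The
  classifier is an in-package bootstrap-aggregated CART forest (Gini
  splits, `mtry = ⌊√p⌋`, default 500 trees) with out-of-bag permutation
  importance, written in C++ because the null calibration refits the
  forest many times. The selection rule is **null-calibrated**: the forest
  is refit on `importance_null_reps = 99` label-shuffled copies, and OTUs
  whose observed importance exceeds the `(1 − alpha)` quantile of the null
  *maximum* importances are selected. This controls the familywise
  false-selection rate at about `alpha = 0.05` and was chosen because the
  literature never states how OTUs are extracted from forest output; a
  transparent `top_k` mode is also provided. Feature order is canonicalized
  internally (sorted OTU ids) so selections are exactly invariant to input
  column order despite the stochastic fitting.
* **IndVal** — for OTU *i* and group *g*, specificity
  `A = mean relabund in g / Σ_g mean relabund` and fidelity
  `B = fraction of g's samples with the OTU present`;
  `IndVal = A·B·100`, scored as the maximum over groups, tested by group-
  label permutation (999 by default, add-one convention) and BH-adjusted
  within the technique.
* **Presence-absence** — detected (≥ 1 read) in more than
  `prevalence_high = 0.5` of samples at one time point and in at most
  `prevalence_zero = 0` at the other, either direction. A pure threshold
  rule: no p-values, no multiplicity.
* **Multiple t testing** — per-OTU paired t (paired across mice when
  pairing is available) on **log10 relative abundances** with a
  pseudocount of half the detection limit (`0.5/depth`). The log transform
  is the package's resolution of the open transform question: proportions
  of overdispersed counts have sample CVs near 1, and at cohort sizes of
  ten mice a raw-proportion t test cannot clear a ×300 Bonferroni factor
  even for taxa lost completely — the transform is variance-stabilizing,
  standard for compositional counts, and leaves the null behaviour intact.
  Correction defaults to Bonferroni (the benchmark's declared convention;
  the literature is ambiguous between Bonferroni and BH, so both are
  implemented and the choice is an explicit argument, never guessed).
  Constant OTUs are skipped with `NA` and never selected.

## 6. The pseudo-F-reduction benchmark

A technique is scored at a transition by `ΔF = F_full − F_reduced`: the
PERMANOVA pseudo-F on Bray-Curtis over the transition's samples, before
and after deleting the technique's selected OTUs. Conventions:

* After removal, samples are **not re-rarefied**; distances are
  recomputed on the remaining counts. Re-rarefaction would confound OTU
  removal with fresh resampling noise.
* `F_full` and `F_reduced` share the same permutation seed, so p-value
  differences reflect composition only.
* Records keep the full (technique × group × transition) factorial;
  pooled summaries and the paired t tests between techniques (paired by
  group and transition) are derived from the records, with unmatched
  pairs dropped under a warning.

## 7. Iron-sensitivity classification

An OTU is **iron-sensitive** iff (a) it is *appreciable at baseline* —
detected in ≥ `appreciable_min_prevalence = 0.5` of baseline samples with
mean baseline relative abundance ≥ `appreciable_min_relabund = 0.001`
(10 reads at depth 10,000) — and (b) *undetectable during LI* in strictly
more than `undetectable_frac = 0.5` of the mice, where a mouse counts as
undetectable only if the OTU has zero reads at **every** LI time point
sampled for that mouse (the stricter of the two possible readings; mice
with no LI samples leave the denominator). A sensitive OTU is
**recovered** iff detected at **any** repletion time point in ≥
`recovery_min_prevalence = 0.5` of the repletion-sampled mice.

Two interpretation choices deserve note. "Appreciable levels" has no
agreed definition; the joint prevalence/abundance floor above is the
package's operationalization, configurable and recorded in the manifest.
"Baseline prevalence" is **sample-level** (fraction of baseline samples
with detection) — the conventional definition — while the LI and
repletion criteria are explicitly per-mouse; a per-mouse any-detection
baseline reading turns out to admit intermittently detected rare taxa
that no one would call appreciable. The classifier is monotone: raising
`undetectable_frac` can only shrink the sensitive set.

## 8. The synthetic cohort generator

`generate_cohort()` draws, per mouse and time point, a
Dirichlet-multinomial sample around a per-mouse expected composition
built on the natural-log scale:

```
log x = base + diet_shift·[post-T0] + s·[LI] + s·[repletion, non-recovering]
        + cage effect + mouse effect,    p = softmax(log x)
```

Defaults state the emulated world and are not tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| `n_otus` | 310 | post-filtering table size of the emulated study |
| `n_mice`, `n_cages` | 10, 2 | two technical-replicate cages of 5 mice |
| `timepoints` | all 7 | full challenge/repletion design |
| `library_size_mean`, dispersion | 20 000, 0.05 | negative-binomial read totals comfortably above the 10 000 rarefaction depth |
| `base_abundance_logmean`, `logsd` | 0, 2 | log-normal species-abundance distribution; a realistic long tail |
| `diet_shift_fraction`, `logfc_sd` | 0.3, 1 | the chow→purified-diet switch is itself a major perturbation |
| `n_sensitive`, `n_recovering` | 6, 3 | the emulated finding: six lost, three return |
| `sensitivity_logfc` | −20 | complete loss: drives plants far below the 1e-4 detection limit (the real effect size is unknown; this is a free parameter, not an estimate) |
| `mouse_effect_sd`, `cage_effect_sd` | 0.3, 0.2 | litter/cage structure; cage effects shared by cage mates |
| `overdispersion` (Dirichlet θ) | 500 | see below |

Sensitive OTUs are planted among OTUs whose expected post-shift relative
abundance is ≥ 0.5% — a clear margin above the classifier's 0.1%
appreciable floor — because the emulated observation is precisely "taxa
appreciable at baseline that vanish under LI"; planting an effect on a
taxon nobody could have called appreciable would make ground truth
unrecoverable by construction, a generator/classifier mismatch rather
than a statistical failure. Diet-shift and sensitive sets are kept
disjoint so the two effects are identifiable at different transitions.

The Dirichlet concentration θ = 500 was set jointly with the rest of the
stated world: θ·p is the effective prior count of an OTU at abundance p,
so at the 0.1% appreciable floor θ = 500 leaves taxa clearly
overdispersed (per-sample CV ≈ √(1/(θp)) ≈ 1.4) yet reliably detectable
at depth 10 000. Much stronger overdispersion (θ ≲ 200) makes taxa at
the floor *intermittent* — absent from half their samples — which
contradicts the world the classifier definitions describe, in which
appreciable taxa are consistently observed at baseline and their LI
disappearance is informative. Real 16S data sets span both regimes;
analysing a strongly intermittent community would require raising the
appreciable floor above 0.1%.

The generator also supplies log-normal per-phase iron measurements
(baseline/repletion high, LI about one order of magnitude lower, sd 0.2
log10 units) and qPCR Ct records in which the treatment arm's target Ct is
shifted by `−log2(fold change)`, making the comparative-Ct estimator
unbiased by construction.

**What a green test does not establish.** The generator emulates the
*statistical shape* of a rarefied OTU table — compositional
overdispersion, random effects, planted presence/absence dynamics. It does
not simulate reads, chimeras, primer or extraction bias, taxonomy errors,
phylogenetic correlation between OTUs, OTU-OTU ecological interactions, or
temporal autocorrelation beyond the static mouse/cage effects. Recovery of
planted effects here therefore validates the pipeline's logic and
calibration, not its behaviour under every pathology of real sequencing
data.

## 9. Numerical conventions

* One RNG stream per cohort from the master seed; per-operation seeds are
  derived deterministically (`(seed·1103 + offset·12289) mod 2³¹−1`) so
  pipeline stages are individually reproducible and the whole pipeline is
  a pure function of (inputs, config, seed).
* Counts are stored as doubles (exact below 2⁵³) to avoid integer
  overflow in sums of squared distances.
* Permutation exceedance comparisons use a 1e-12 absolute tolerance.
* The exact Wilcoxon branch uses the signed-rank null CDF; the brute-force
  2ⁿ sign enumeration lives in the test suite as an independent oracle,
  as do definition-level re-implementations of PERMANOVA, IndVal and
  Bray-Curtis.

## 10. Known limitations

* PERMANOVA is one-factor; no interactions, no PERMDISP companion test,
  and the default free permutation ignores the repeated-measures
  structure (deliberately, to match field practice — use `strata`
  otherwise).
* No phylogenetic diversity metrics and no compositional differential-
  abundance models (ALDEx2/ANCOM style); they are outside this pipeline's
  scope.
* The random forest is a minimal two-class implementation intended for
  OTU selection at cohort scale (tens of samples), not a general-purpose
  learner.
* `rarefied_depth` is dropped when OTU columns are removed from a table,
  since constant row sums no longer hold; the benchmark relies on this
  behaviour.
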