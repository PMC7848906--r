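Package: ferromic
Title: Longitudinal Gut Microbiome Analysis of Dietary Low-Iron Challenge
Version: 0.1.0
Authors@R: person("Ferromic", "Maintainers", email = "maintainers@ferromic.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal 16S rRNA OTU-table analysis of dietary
    iron-depletion studies in mice: mothur shared-file input, post-clustering
    filtering and rarefaction, alpha diversity (inverse Simpson, richness) and
    Bray-Curtis beta diversity, PERMANOVA and NMDS ordination, paired
    nonparametric time-point statistics with multiplicity correction,
    comparative threshold-cycle (Ct) gene-expression analysis, four
    OTU-selection techniques (random forest, indicator value, presence-absence,
    multiple t testing), a pseudo-F-reduction benchmark of those techniques,
    and classification of iron-sensitive OTUs into recovered and non-recovered
    sets. A Dirichlet-multinomial cohort simulator with planted ground truth
    makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
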