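Package: dyadnet
Title: Interkingdom Co-Abundance Networks for Mother-Infant Microbiome Dyads
Version: 0.1.0
Authors@R: person("dyadnet", "developers", email = "dev@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired bacterial (16S) and fungal (ITS2)
    amplicon count tables from breastfeeding mother-infant dyads. Provides
    centered log-ratio (CLR) normalization and Aitchison, Bray-Curtis and
    unweighted UniFrac beta diversity, principal coordinates analysis,
    PERMANOVA with sequential sums of squares, a related-versus-unrelated
    dyad distance test based on random derangements, symmetric Procrustes
    congruence with Monte-Carlo significance, per-taxon Wilcoxon tests with
    Hodges-Lehmann shift estimates and Benjamini-Hochberg FDR, and
    prevalence-filtered interkingdom Spearman co-abundance networks with an
    edges-per-node connectedness statistic. A Gaussian-copula synthetic
    cohort generator with planted interkingdom correlations makes every
    stage testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    phyloseq,
    biomformat
Config/testthat/edition: 3
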