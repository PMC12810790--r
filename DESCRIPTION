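Package: monomix
Title: Detection-Aware Differential Proteomics for Two-Organism Cocultures
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative label-free data-dependent acquisition (DDA)
    proteomics of two-organism cocultures, such as an alga hosting a
    heterotrophic bacterium that contributes only a small share of total
    biomass. Implements peptide-to-protein parsimony inference, central-tendency
    normalization and log2 roll-up to gene-level abundances, per-organism
    quantile normalization with explicit missing-value handling,
    limit-of-quantitation-gated Welch differential expression with
    Benjamini-Hochberg correction, k-means clustering, principal component
    analysis, hypergeometric term enrichment with Holm correction, and
    sequence-based physicochemical profiling (isoelectric point, GRAVY
    hydropathy, molecular weight). A stochastic top-N acquisition simulator
    generates two-proteome experiments with fixed injection load, mono-mix
    controls, optional fraction concatenation, and ground truth, reproducing
    the abundance-dependent detection suppression that confounds naive
    monoculture-versus-coculture comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Normalization, DifferentialExpression,
    Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
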