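Package: dadmet
Title: Consensus-Based Druglikeness and ADMET Screening of Small Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens small-molecule compounds by pooling molecular
    descriptor predictions and qualitative ADMET calls from multiple
    chemoinformatics platforms: numeric descriptors are combined by
    averaging over reporting platforms, qualitative calls by majority
    vote with a configurable tie-break.  Compounds are scored against
    five criteria (druglikeness rule filters plus QED, medicinal
    chemistry filters, bioavailability, plasma protein binding, and
    toxicity) and selected when at least three of five pass.  Includes
    the validation toolkit for such screens: paired regression metrics
    with a mean-only baseline, OLS fits with coefficient confidence
    intervals, confusion-matrix statistics, virtual screening
    enrichment factors and ROC-AUC, symmetry-aware docking pose RMSD,
    mean confidence intervals, Welch t and two-sample
    Kolmogorov-Smirnov tests, plus seeded generators for synthetic
    platform tables and ranked actives/decoys sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ChemmineOB,
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
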