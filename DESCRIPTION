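Package: crmclass
Title: Classification of CBP-Bound Cis-Regulatory Elements from Multi-Factor ChIP Signal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies transcription co-activator (CBP/p300) binding sites into
    regulatory-element classes (active promoters, active and inactive enhancers,
    Polycomb response elements, insulators) from genome-wide binned ChIP signal
    tracks. Implements percentile-threshold peak calling on median-smoothed
    log2 IP/input enrichment, a top-three-consecutive-bins binding summarizer
    over many factor and histone-modification tracks, PCA with Ward hierarchical
    clustering of binding profiles, class characterization (gene-feature
    assignment, expression tertiles, overlap statistics with random-region
    controls, factor correlations, developmental expression profiles), oriented
    H3K27me3 boundary-spreading metaprofiles around insulator-like sites,
    ChIP-qPCR delta-delta-Cq fold analysis, and k-mer word enrichment against
    A/T-matched control sequences. Ships a synthetic-data generator with planted
    element archetypes and ground truth so the whole pipeline is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    stats,
    utils,
    jsonlite,
    yaml,
    mclust,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    generics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
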