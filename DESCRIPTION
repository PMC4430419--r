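Package: mitomorph
Title: Quantitative Mitochondrial Network Morphometry and Mitotoxicity Assay Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis and assay-statistics toolkit for quantifying drug-induced
    mitochondrial toxicity in Caenorhabditis elegans. Segments mitochondrial networks
    in fluorescence microscopy stacks (slice triage, maximum-intensity projection,
    rolling-ball background subtraction, local contrast enhancement, multi-scale
    Laplacian enhancement, Yen autothresholding, size-filtered particle extraction),
    computes ImageJ-convention shape descriptors and gray-level co-occurrence matrix
    texture features, clusters drug phenotypes with z-scored clustergrams and k-means,
    and implements qPCR absolute and relative quantification against a plasmid
    standard curve, pooled-variance and Welch two-sample tests, F-tests,
    oxygen-consumption slope estimation and quinone redox ratios. Ships seeded
    simulators for microscopy stacks with ground truth, feature tables, Ct datasets
    and O2 traces so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    igraph,
    ape,
    pracma,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
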