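Package: applehypoxia
Title: Long-Term Hypoxia Transcriptome Analysis for Postharvest Apple Storage
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for time-course RNA-seq studies of apple fruit
    stored under normoxic and hypoxic (controlled-atmosphere) regimes, with and
    without the ethylene-perception inhibitor 1-MCP. Provides median-of-ratios
    normalization, a simplified negative-binomial Wald test with Bonferroni
    control, the contrast-set logic that classifies hypoxia-upregulated genes
    into CA-only/MCPCA-only subsets and per-timepoint "n-degron" and "ethylene"
    response sets, tree-ensemble (GENIE3-style) transcription-factor network
    inference with top-k thresholding and a TF-role classifier, IUPAC consensus
    scanning for the hypoxia-responsive promoter element (HRPE, GCCVCYGGTTTY)
    and the N-terminal MCGGAI/V degron, hypergeometric gene-set enrichment, and
    a negative-binomial count simulator that emulates the 7-treatment storage
    design with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
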