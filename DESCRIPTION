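Package: isletAging
Title: Quantification of NF-kB Heterogeneity and Proliferative Decline in
    Pancreatic Beta-Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify age-related heterogeneity of NF-kB reporter
    activity and the proliferative decline of pancreatic beta-cells from
    multi-channel 3D islet image stacks, single-cell and bulk RT-qPCR cycle
    threshold tables, and flow-cytometry event tables. Provides per-cell
    nuclear fluorescence quantification (center-plane selection, DAPI-normalized
    GFP), GFP-high/low classification against a per-islet threshold, FUCCI and
    mosaic-transgenesis proliferation scoring, censored single-cell qPCR
    detection statistics with Pearson chi-square comparisons, delta-delta-Ct
    bulk fold changes, kernel-density splitting of bimodal FACS intensity
    distributions, and a seeded synthetic-islet generator with ground truth for
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    tiff,
    rlang,
    S4Vectors,
    SummarizedExperiment,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, SingleCell, Visualization, QualityControl
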