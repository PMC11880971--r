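Package: tilePheno
Title: Tile-Based Multiplex IHC Phenotyping of Pancreatic Ductal Adenocarcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intratumor heterogeneity of pancreatic ductal
    adenocarcinoma from serial-section immunohistochemistry. Co-registered
    binary positive-pixel masks for a seven-marker subtype panel (GATA6,
    CLDN18, TFF1, MUC16, S100A2, KRT17, PanBS) plus pan-cytokeratin are cut
    into fixed-size square tiles over pathologist annotations; per-tile
    positive-pixel proportions are filtered, log-transformed, reduced by PCA
    and clustered by k-means with silhouette model selection into named tile
    phenotypes (Classical, Intermediate, Basal.MUC16, Basal.S100A2).
    Per-tumor composition, presence and predominance calls, phenotype
    co-occurrence (Fisher), predominant-phenotype shifts across slides, and
    survival stratification by minor basal-clone presence (Kaplan-Meier,
    log-rank, Cox) are provided, together with H-score based marker-triage
    rules and a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    cluster,
    survival,
    mgcv,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
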