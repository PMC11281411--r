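Package: momnet
Title: Multiomics Co-Occurrence Network Analysis for Microbiome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and compares Spearman co-occurrence networks across gut
    virome, bacterial and metabolite abundance layers, optionally augmented
    with clinical symptom-scale items. Provides RPKM normalisation and
    abundance-retention filters, alpha/beta diversity with PERMANOVA,
    rank-test plus LDA-effect-size differential abundance, correlation
    network construction with Benjamini-Hochberg FDR control, and the full
    topological analysis used to contrast patient and control networks:
    centralities, Louvain modules, Zi-Pi node roles, degree power-law fits,
    module overlap and symptom-module concentration. A synthetic-data
    generator with planted correlation blocks, group effects and
    symptom-factor loadings supplies ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
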