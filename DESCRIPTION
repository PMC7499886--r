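Package: temdyn
Title: Transposable-Element Small RNA and DNA Methylation Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of 24-nt small interfering RNA (siRNA)
    production and RNA-directed DNA methylation over transposable elements
    (TEs) across plant embryogenesis. Provides a ground-truth synthetic-data
    generator (miniature genome, stage-resolved small RNA alignment tables,
    per-cytosine methylomes, nucleosome-occupancy tracks), rich-get-richer
    reassignment of multi-mapping small RNA reads, RPM normalisation and
    per-TE quantification, temporal classification of TEs with a
    VEV-constrained Gaussian mixture model selected by BIC, weighted
    methylation and differentially methylated region (DMR) calling with a
    root-mean-square goodness-of-fit test, scale-region profile matrices,
    nucleosome-profile k-means grouping, and the chromatin association
    statistics used to relate siRNA output to chromatin state.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
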