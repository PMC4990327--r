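Package: ctprofiler
Title: Cancer Transcriptomic Profiles by Ternary Gene-Expression Deviation Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-expression deviation profiling of cancer cohorts.
    Normalized log2 expression matrices are mean-centered per probe and
    discretized into three levels (-1, 0, +1) at a cut of 0.43 standard
    deviations, chosen so that the three levels are equally populated under
    Gaussian deviations. Discretized sample profiles are clustered (k-means or
    a one-dimensional self-organizing map) into three Cancer Transcriptomic
    Profiles (CTPs), each summarized by a centroid "target vector". New
    samples, from the same or a different cancer type, are assigned to the
    CTP with the highest Pearson correlation, and assignments are visualized
    by barycentric (de Finetti) mapping into an equilateral triangle. The
    package also provides cohort statistics (cluster diameter, partition
    overlap, gene-subset robustness), synthetic cohort generators with
    planted group structure, and the pure-noise null simulation used to show
    that CTP structure does not arise from random expression fluctuation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ggplot2,
    optparse
Config/testthat/edition: 3
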