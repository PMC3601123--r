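Package: boutiquenorm
Title: Normalization and Expression Cataloging for Boutique Microarrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Probe-level processing and normalization methods for small
    custom ("boutique") microarrays whose probe content is biased toward a
    single gene family, so that most genes can shift together between
    conditions and the distributional assumptions of whole-array
    normalization fail. Provides RMA-style background correction, quantile
    normalization and median-polish summarization; MAS5-style
    Present/Marginal/Absent detection calls with an exact signed-rank
    null; three boutique normalization schemes (stable-gene based quantile
    normalization, and per-replicate-group RMA rescaled by the median of
    always-absent probe sets or of invariant genes); detection-based
    expression catalogs, differential expression with Benjamini-Hochberg
    correction, co-expression screening, average-linkage clustering and
    reference-gene stability ranking; an evaluation harness against
    whole-array reference normalization; and a probe-level simulator with
    full ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
biocViews: Microarray, Preprocessing, Normalization, GeneExpression,
    DifferentialExpression, QualityControl
RoxygenNote: 7.3.3
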