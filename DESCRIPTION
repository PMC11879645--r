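Package: loopscape
Title: Chromatin Loop Calling from Hi-C Contact Maps by Scale-Space Curvature Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects chromatin loops in binned Hi-C contact matrices by testing
    the statistical significance of surface curvature in scale space. Windows of
    the contact map are log-transformed, median-matched between two cell types or
    conditions, stripped of near-diagonal bands, smoothed with Gaussian kernels at
    a chosen bandwidth, and screened for pixels whose Hessian eigenvalues are
    simultaneously significantly negative (peaks) with family-wise error control
    via an independent-blocks critical value. Significant pixels are clustered
    into loops, and loops are labelled as shared or condition-specific by
    comparing clusters between the two conditions. Includes aggregate peak
    analysis (APA), loop-set overlap and promoter-anchoring summaries for
    parameter tuning, and a synthetic Hi-C generator with planted loops for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse, yaml
Config/testthat/edition: 3
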