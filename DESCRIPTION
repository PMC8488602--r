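Package: omicflux
Title: Condition-Specific Metabolic Modeling with Transcriptome-Constrained
    Regularized FBA and Multi-Omic Feature Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates transcriptomic fold changes into a genome-scale
    metabolic model through a logarithmic bound-scaling map, solves
    norm-2-regularized bi-level flux balance analysis for paired objectives
    across growth conditions, fuses transcript and flux fold changes into a
    multi-omic matrix, and extracts condition- and pathway-level features via
    principal component analysis, silhouette-guided k-means clustering, LASSO
    regression, and Pearson correlation analysis. Ships a self-contained
    synthetic cyanobacterium-like toy model and transcriptome generator so the
    whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    quadprog,
    glmnet,
    cluster,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
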