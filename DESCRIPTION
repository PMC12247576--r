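Package: morphopool
Title: Precision Analysis for Cluster Scanning Brain Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies test-retest measurement error of MRI-derived brain
    morphometric estimates (regional volumes, cortical thickness,
    gray-to-white matter signal intensity ratio) and the precision gained by
    pooling estimates from multiple rapid structural scans acquired in rapid
    succession ("cluster scanning"). Provides a SummarizedExperiment-based
    container for per-scan morphometric estimates, readers for FreeSurfer
    stats tables and a canonical long CSV, a hierarchical multiplicative
    noise simulator with controllable inter-scan error autocorrelation, the
    percent-error statistic and pooled-estimate error summaries,
    square-root-of-k expected-error benchmarks and equicorrelation closed
    forms, autocorrelation estimation from pooled session differences,
    paired contrasts between pooling schemes (pooling curves, break and
    multi-resolution moderators, subgroup summaries), and translation of
    measurement precision into longitudinal design quantities (detectable
    change, required sample size, scan-time budgets).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Neuroimaging, QualityControl
RoxygenNote: 7.3.3
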