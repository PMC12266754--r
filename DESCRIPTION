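Package: irpipe
Title: Immune Resilience Metrics from Transcriptomic Signatures and T-Cell Counts
Version: 0.1.0
Authors@R:
    person("IR Pipeline", "Maintainers", email = "irpipe@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify immune resilience (IR) from bulk transcriptomes
    and T-cell counts: oriented gene-set z-scoring with median-split strata,
    SAS-1/MAS-1 IR profiles and TCF7 strata, immune health grades (IHG) from
    absolute CD4+/CD8+ counts, a pathogenic-triad burden composite,
    longitudinal preserver/reconstituter/degrader trajectory classification,
    proportional-hazards modelling with a hazard-equivalence-age statistic,
    and FDR-controlled feature screens. A synthetic-cohort simulator with
    planted effects makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
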