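Package: tearmiR
Title: Tear-Fluid miRNA RT-qPCR Profiling and Candidate Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for RT-qPCR miRNA profiling of pooled tear-fluid
    samples in Parkinson's disease and atypical Parkinsonian syndromes.
    Implements three-level amplification-status calling from replicate cycle
    threshold (CT) values, UpSet-style presence/absence intersection analysis
    with disease-exclusive candidate sets, clinical correlation and regression
    statistics with Fisher-z confidence intervals, literature and tissue
    cross-referencing of candidate miRNAs, and signed hypergeometric
    overrepresentation analysis of predicted target genes. A synthetic-data
    generator with known ground truth makes every stage testable without
    access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
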