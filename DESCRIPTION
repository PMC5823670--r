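Package: tosca
Title: Tumor-Only Somatic Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tumor-only somatic variant analysis for targeted cancer
    sequencing cohorts without matched normal samples. Provides a
    per-sample allele-frequency flag taxonomy (quality, depth,
    population-database and impact flags), a configurable filter funnel
    that removes germline and artifactual calls, mutation recurrence
    statistics at gene, exon and amino-acid resolution, spatial hotspot
    cluster detection along protein coordinates with a background null
    model, penalized Cox regression with per-cluster refits across
    endpoint/stage/site analysis groups, and evidence-based gene-panel
    scoring. A fully parameterized synthetic-cohort generator with
    ground-truth labels (germline, somatic, artifact; planted prognostic
    hotspots) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    grDevices,
    stats,
    survival,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
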