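Package: wardflow
Title: Data-Driven Clinical Decision Support Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workflow engine for data-driven clinical decision support.
    Declarative plans describe patient journeys as directed graphs of steps,
    each combining a schema-validated data input with a clinical risk score,
    a logical rule set, or a serialized predictive model, and a decision that
    routes the journey onward. Plans are executed over static stores in
    hourly replay or over near-real-time message streams. Includes a CURB65
    community-acquired-pneumonia severity application with NHS severity
    banding, a synthetic hospital admissions feed with known ground truth,
    a retrospective severity-comparison evaluation pipeline, model
    performance metadata, perturbation-based local explanations, and
    Mermaid/HTML report renderers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    pROC,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    DBI,
    RSQLite,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
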