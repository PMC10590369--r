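Package: traceproc
Title: Weekly Topic Processes and Actor Clustering from Trace Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw platform event logs (actor, date, target-action pair)
    into actor-week bag-of-words documents, fits latent Dirichlet allocation
    topic models with BIC-based model selection, aggregates topics into
    user-defined themes, assembles each actor's weekly theme process, computes
    an activity-weighted Jensen-Shannon dissimilarity between actors, clusters
    actors with complete-linkage agglomerative clustering, and summarises the
    resulting cluster-level weekly processes. Includes a seeded synthetic
    event-log generator with planted cluster structure so the whole pipeline
    can be exercised and validated without access to confidential platform
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    ape,
    methods,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
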