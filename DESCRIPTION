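Package: comorbnet
Title: Comorbidity Network Analysis of ICD-10 Medical Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating chronic-disease comorbidity
    networks from ICD-10 visit records. Raw records are deduplicated,
    validated against ICD-10 coding rules, recoded into merged disease
    categories, and filtered into a binary patient-by-disease matrix. The
    network is estimated per sex stratum by eLasso: node-wise l1-regularized
    logistic regression over a regularization path with extended BIC model
    selection and AND/OR-rule symmetrization. Downstream analyses include
    weighted node centrality (strength, closeness, betweenness), fast-greedy
    modularity-based community detection with a resolution parameter, and
    descriptive prevalence and age-distribution tables. A synthetic-data
    module generates Gibbs samples from known Ising models and messy raw
    record files with an exact exclusion ledger, so every pipeline stage is
    testable without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
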