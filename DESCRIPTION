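Package: fcnets
Title: Sex and Age Effects on Resting-State Functional Connectivity and Brain Graph Topology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mass-univariate analysis of resting-state functional
    connectivity (FC) in a young-adult cohort: construction of Fisher
    z-transformed region-pairwise FC tables from ROI time series, per-edge
    backward stepwise regression over the five-model family spanned by sex,
    age and their interaction with Bonferroni family-wise control,
    covariate-augmented refits and sex-stratified age slopes, and per-subject
    graph-theoretic analysis (nodal clustering, local efficiency, harmonic-mean
    characteristic path length, largest connected component, small-worldness
    against degree-preserving rewiring nulls) across a proportional
    graph-density grid. A synthetic-cohort generator with known embedded
    sex/age/interaction effects stands in for restricted subject-level data so
    the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
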