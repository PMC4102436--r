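Package: minenv
Title: Minimal Growth Environments for Genome-Scale Metabolic Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the minimal nutritional environment (MINENV) of a
    microorganism from its genome-scale metabolic model. A two-stage
    mixed-integer linear program first finds the smallest number of
    exchange metabolites whose uptake sustains a nominal biomass flux,
    then disambiguates among equally small media by preferring low
    molecular-weight compounds, yielding a unique, reproducible minimal
    environment per organism together with its core of critical
    (irreplaceable) metabolites. Includes flux balance analysis with
    gene-protein-reaction deletions, readers and writers for SBML/FBC
    and COBRA-style JSON models, ecological analyses relating nutritional
    fastidiousness to co-occurrence (Jaccard similarity curves, split-half
    aggregate-media distances, growth on aggregate media, covariate
    correlations), and seedable synthetic model and community generators
    with an exhaustive brute-force oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr,
    knitr
SystemRequirements: C++17
Config/testthat/edition: 3
biocViews: Metabolomics, SystemsBiology, Network, Software
RoxygenNote: 7.3.3
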