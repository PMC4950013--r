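Package: valuewave
Title: Sinusoidal Circumplex Analysis of Value Profiles and Polygenic Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether an external variable maps onto the
    circular (circumplex) structure of Schwartz's ten human value types.
    Scores value surveys (ipsatization, value-type aggregation, Cronbach's
    alpha), builds polygenic scores from GWAS summary statistics by p-value
    thresholding, greedy linkage-disequilibrium pruning and log-odds-weighted
    allele averaging, fits a box-constrained sinusoid to the ordered profile
    of value-type correlations, summarises fit with the Sinusoidal Fit Index
    (SFI), and calibrates SFI false-positive rates by Monte-Carlo simulation
    under uniform and truncated-normal nulls. A synthetic-data module
    generates circumplex-structured survey responses, external traits with a
    target sinusoidal correlation profile, and genotype/trait pairs with a
    target polygenic correlation, so the whole pipeline runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
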