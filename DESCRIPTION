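Package: pcmkit
Title: Phylogenetic Comparative Analysis of Genome Size Evolution in
    Bacteria and Archaea
Version: 0.1.0
Authors@R:
    person("Carolina", "Rivera", email = "crivera@example.org",
           role = c("aut", "cre"))
Description: Tools for phylogenetic comparative analysis of continuous
    genomic traits across microbial phylogenies: maximum-likelihood fitting
    and comparison of trait-evolution models (Brownian motion,
    Ornstein-Uhlenbeck, Early-Burst, Pagel's lambda, trend diffusion, drift,
    white noise), phylogenetic-signal statistics (Blomberg's K with a
    permutation test; Pagel's lambda, kappa and delta with profile-likelihood
    intervals), non-phylogenetic and phylogenetic generalized least squares
    regression with jointly estimated branch-length transforms, a pairwise
    dN/dS filtering and aggregation protocol with a self-contained
    Nei-Gojobori counting estimator, seeded synthetic-data generators for
    every stage, and a config-driven command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
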