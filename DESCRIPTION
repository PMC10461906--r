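Package: expadequacy
Title: Relative and Absolute Fit of Trait-Evolution Models for Comparative
    Gene Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-gene maximum-likelihood fitting of Brownian motion,
    Ornstein-Uhlenbeck and Early Burst models to species-level gene
    expression on an ultrametric phylogeny, AIC-based model selection, and
    absolute model-adequacy assessment by parametric bootstrap: branch
    lengths are rescaled with the fitted parameters into a "unit tree" on
    which phylogenetic independent contrasts should be i.i.d. standard
    normal, five summary statistics of the contrasts are compared with
    their simulated null distributions, and two-tailed Monte Carlo
    p-values flag genes the best model describes poorly. Includes a
    synthetic-data generator (trees, replicate-level expression matrices,
    missing species, rate-shift violations) so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
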