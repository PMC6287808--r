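Package: conifergs
Title: Stochastic Simulation of Genomic and Forward Selection in Conifer Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of a conifer breeding program and the
    machinery needed to compare genomic selection against conventional forward
    selection. Simulates a 150 cM chromosome with neutral SNP panels and
    gamma-distributed QTL effects through historical, extended and recent
    population phases; estimates breeding values by pedigree BLUP (Henderson's
    mixed-model equations) and genomic breeding values by a BayesC Gibbs
    sampler with Garrick de-regression weights; accounts genetic gain per
    generation and per year for four selection schemes; and schedules
    multi-rotation deployment of seedlings or somatic-embryogenesis clones to
    quantify the gain delivered to the forest over eight 25-year rotations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
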