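Package: aflphylo
Title: AFLP Phylogenetics and Hybrid Detection from Dominant Markers
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for phylogenetic analysis of amplified fragment length
    polymorphism (AFLP) data and other dominant binary markers: peak-height
    scoring with replicate-based mismatch error rates and threshold
    optimization, Nei-Li restriction-fragment distances, neighbour-joining
    tree estimation with locus-bootstrap support, a leave-one-species-out
    homoplasy excess test for detecting hybrid taxa, and a two-state
    restriction-site likelihood engine with ascertainment-bias correction,
    Shimodaira-Hasegawa topology tests and harmonic-mean Bayes factors.
    Includes a fully parameterised synthetic AFLP data generator (species
    trees, binary characters, planted hybrid taxa, noisy peak heights with
    replicates) that serves as a ground-truth test harness for the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
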