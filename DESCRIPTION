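Package: soilresponders
Title: Bacterial Community Response Analysis for Pollutant-Spiked Soils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of 16S rRNA gene amplicon OTU tables and community
    fingerprints from pollutant-spiking experiments in soil. Implements
    Pearson-correlation community similarity with UPGMA clustering and
    feature-bootstrap support, the percent-dissimilarity d statistic with an
    exhaustive or Monte-Carlo permutation test, rarefaction and
    rarefaction-normalized diversity indices (Chao1, Shannon, Pielou),
    a taxonomy-sweeping binomial-GLM responder test with Tukey-style pairwise
    contrasts, explicit rules for detecting diminished OTUs, neighbor-joining
    responder phylogenies with branch compression, and a synthetic community
    generator emulating a two-soil spiking experiment for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    multcomp,
    mvtnorm,
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
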