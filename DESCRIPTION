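Package: dimorph
Title: Detection of Size Dimorphism in Morphometric Measurement Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Maximum-likelihood comparison of unimodal normal and
    two-component normal-mixture models on log10-transformed linear
    measurements, with small-sample AICc model selection and Akaike
    weights; posterior morph assignment with an ambiguity zone;
    correlation-scaled PCA and k-means cluster concordance; within-morph
    allometric regression and coefficient-of-variation contrasts; and a
    seeded synthetic fossil-population generator (dimorphic and
    monomorphic traits, allometric coupling, breakage missingness) so the
    whole pipeline can be exercised and power-tested without external
    data. Developed around the dicynodont Placerias hesternus, whose
    maxillary caniniform process shows two size morphs in the Placerias
    Quarry population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    tibble,
    dplyr,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
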