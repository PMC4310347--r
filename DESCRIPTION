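Package: phylomethyl
Title: Phylogenetic Signal and Correlated Evolution of Global DNA
    Cytosine Methylation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Phylogenetically-informed comparative analysis of global DNA
    cytosine methylation (%mC) across plant species. Curates species-level
    methylation estimates from HPLC chromatogram peak areas, computes four
    complementary phylogenetic-signal statistics (Moran's I, Abouheif's
    Cmean, Blomberg's K and Pagel's lambda) with randomization tests, and
    tests for correlated evolution between methylation level and genome
    size (C-value) via Felsenstein's phylogenetically independent
    contrasts and a permutation-tested regression through the origin.
    Includes Brownian-motion and lambda-model trait simulators and a
    generator of study-like synthetic data sets for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phytools,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
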