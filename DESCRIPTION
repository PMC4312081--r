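Package: lemmingdiet
Title: DNA Metabarcoding Analysis of Lemming Winter Diets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing herbivore diets from trnL P6-loop DNA
    metabarcoding of fecal pellets, built around the winter diets of the two
    sympatric High-Arctic lemmings (collared, Dicrostonyx groenlandicus, and
    brown, Lemmus trimucronatus). Provides in-silico PCR formatting of plant
    reference libraries, taxonomic assignment of sequence variants with
    local-flora cleaning, consumer species identification from amplicon
    length, fusion of a vascular-biased and a universal plant marker into
    per-sample diet profiles, niche statistics (Schoener overlap, Shannon
    trophic niche width, individual specialization with resampling,
    rank-transform and aligned-rank ANOVA), Manly resource selection ratios
    with sampled availability, and a Dirichlet-multinomial synthetic-data
    generator with known ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
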