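Package: transportome
Title: Expression-Uptake Correlation Analysis for Sugar Transporter
    Deorphanization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate transporters for orphan sugar substrates
    by correlating sugar-uptake rates, measured from supernatant depletion
    time courses across matched induction conditions, with transporter gene
    expression profiles via Pearson-distance hierarchical clustering.
    Includes neighbor-joining phylogenetics with Poisson-corrected
    pairwise-deletion distances and bootstrap support for clade assignment
    of uncharacterized transporters, 2^-ddCt relative qPCR quantification,
    the group-comparison decision procedure used for replicate assay data,
    and a seeded synthetic-transportome simulator whose additive uptake
    model (observed uptake is the sum of the individual transporter
    contributions) makes every pipeline stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
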