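Package: commassembly
Title: Null-Model and Distance-Based Statistics for Microbial Community Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for studying the assembly of microbial communities from
    taxa-by-sample tables: a normalized checkerboard co-occurrence (CC) score
    tested against the fixed-fixed (SIM9) swap null, a generalized Morisita
    abundance-overlap (MA) score tested against the IT read-reallocation null,
    Mantel rank-correlation tests of distance decay, stepwise multiple
    regression on distance matrices with permutation significance and
    leave-one-sample-out cross-validation, coefficient-of-variation profiles
    contrasting taxonomic and functional variability, core-biome and
    collector's curves, and a seeded generator of study-shaped synthetic
    datasets with known segregation, distance-decay and environmental effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    vegan,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
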