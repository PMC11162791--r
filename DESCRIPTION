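Package: seloligo
Title: Design of Precursor-Selective 2'-OMe/LNA Antisense Oligomers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing short (default 13-nt) 2'-O-methyl/LNA
    antisense oligomers that selectively block Dicer processing of one member
    of a pair of near-identical pre-miRNA paralogs. Annotates pre-miRNA
    hairpins (apical loop, Dicer cleavage bonds), scores candidate oligomers
    with nearest-neighbor RNA/RNA duplex thermodynamics, screens off-targets
    with an exact ungapped mismatch search over a k-mer indexed transcriptome,
    and runs an exhaustive k-mer elimination pipeline that yields
    transcriptome-null negative-control oligomers. Includes seeded synthetic
    fixture generators emulating paralogous hairpin geometry and background
    transcriptomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
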