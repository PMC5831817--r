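Package: parahoxmap
Title: Pairwise-Similarity Classification of ParaHox Proteins Against Hox Paralog Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An alignment-free-of-multiple-alignments approach to classifying
    homeodomain proteins: profile-based retrieval of Hox/ParaHox family members,
    exact Smith-Waterman all-against-all local alignment with Karlin-Altschul
    E-values, force-directed similarity-map layout with E-value cutoffs, and
    connectivity-based assignment of each ParaHox group (Gsx, Pdx, Cdx) to its
    most similar Hox paralog group. Includes a paralog-family simulator with
    controlled rate heterogeneity and a neighbor-joining contrast that exhibits
    long-branch attraction on fast-evolving groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
VignetteBuilder: knitr
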