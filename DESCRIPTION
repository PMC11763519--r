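Package: orsite
Title: Conservation Screening of Olfactory Receptor Ligand-Binding Cavity
    Residues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for screening odorant-responsive olfactory receptors (ORs)
    and the ligand-binding-cavity residues that determine their specificity.
    Implements the Grantham physicochemical amino-acid distance from first
    principles, maps reference cavity positions onto multiple sequence
    alignment columns, and tests per-site whether a small foreground set of
    co-responsive receptors is more conserved (lower mean pairwise Grantham
    distance) than the full receptor repertoire, by Mann-Whitney, Welch t or
    subset-permutation tests. Also provides candidate filtering of
    differential-expression tables against an OR annotation, normalization
    and significance testing of dual-luciferase reporter plates (odor
    response and mutant-versus-wild-type analysis), and seeded synthetic
    generators for receptor families, count matrices and reporter plates so
    the whole pipeline can be exercised and power-checked without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
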