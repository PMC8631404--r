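Package: amcpipe
Title: Integration of Heterogeneous Brain Proteomics and Metabolomics into
    Adjusted Molar Concentrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts heterogeneous mass-spectrometry protein quantifications
    (LFQ, iBAQ, TMT, SILAC) and literature metabolite measurements into
    unified, housekeeping-normalized molar concentrations. Implements
    gene-name synonym resolution over a co-listing graph, in-silico tryptic
    digestion for detectability correction, the total-protein-mass
    ("proteomic ruler") copy-number and concentration estimation,
    housekeeping-median normalization, metabolite unit standardization and
    tissue compartment volume-fraction mixing, RNA-to-protein conversion
    ratios, and a statistical validation battery (variability and
    specificity scores, Kruskal-Wallis with Conover post hoc, two-group
    location and scale tests with permutation calibration, differential
    concentration selection). A synthetic multi-study generator with known
    ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Biostrings,
    car,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
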