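Package: ramacodon
Title: Codon-Specific Ramachandran Plot Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds codon- and secondary-structure-annotated backbone dihedral
    angle distributions from protein structures and coding sequences, and tests
    whether synonymous codons differ in their backbone angle distributions.
    Provides wrap-aware angle arithmetic on the torus, kernel density estimation
    with a Gaussian kernel applied to the torus distance, an L1 distance
    statistic between estimated densities, a permutation two-sample test with
    bootstrap aggregation over equalized sample sizes, Benjamini-Hochberg false
    discovery rate control, redundancy filtering of protein sequences by
    farthest-first traversal, codon assignment via global alignment of
    translated coding sequences, an uncertainty-aware multidimensional scaling
    of codon distance matrices, confidence-banded Ramachandran contour plots,
    and a synthetic von Mises sample generator for validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
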