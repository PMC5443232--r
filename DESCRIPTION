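Package: novopan
Title: Habitat-Aware Comparative Pangenomics of Novosphingobium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A comparative-genomics workflow for the bacterial genus
    Novosphingobium: protein ortholog clustering by reciprocal best hits
    (BDBH) and COG-triangles at identity/coverage thresholds, core- and
    pangenome rarefaction with Tettelin-style curve fits, habitat-core and
    habitat-specific gene-set algebra with pathway-completeness screens,
    fragment-based and ortholog-based average nucleotide identity (ANI),
    Pearson-correlation dendrograms and Poisson-corrected neighbor-joining
    trees with bootstrap, protein-interaction network topology statistics
    (degree distribution, per-degree clustering, neighborhood connectivity,
    power-law exponents, hub identification), and habitat-level genome
    statistics. A synthetic-data module generates pangenome collections,
    scale-free and hierarchical-modular graphs, and block-structured trait
    matrices with planted ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    ape,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
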