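Package: pangtree
Title: Reference-Tree Variant Cataloguing for Pangenome Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Defines and catalogues genetic variants in a bidirected pangenome
    graph against a reference tree: a spanning tree that contains every node of
    the graph and includes the linear-reference walk as a branch. Edges absent
    from the tree are biallelic variant edges with well-defined alleles,
    positions, types (SNP, MNP, insertion, deletion, replacement, duplication,
    inversion) and per-haplotype genotypes derived from GFA walks. Includes
    GFA 1.0/1.1 reading and writing, pinch-point superbubble detection with a
    triallelic taxonomy, an extended VCF writer, a graph simplifier for
    visualisation, and a pangenome simulator with planted ground-truth
    variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
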