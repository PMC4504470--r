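Package: cyanodelim
Title: GMYC Photobiont Delimitation, Haplotype Networks and
    Community-Environment Analysis for Cyanolichen Symbioses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delimiting cyanobacterial photobiont lineages from
    ultrametric gene trees with the generalized mixed Yule-coalescent (GMYC)
    model (null, single- and multiple-threshold variants with likelihood ratio
    tests), for summarising delimitation uncertainty across posterior tree
    samples into a pairwise co-assignment matrix, and for deriving a consensus
    partition by k-medoids clustering under the optimum average silhouette
    width criterion. Also provides haplotype collapsing and per-group genetic
    diversity statistics (segregating sites, haplotype and nucleotide
    diversity), statistical-parsimony haplotype networks with gaps readable as
    a fifth character state, and locality-level community ecology: Sorensen and
    Bray-Curtis dissimilarities, ANOSIM with permutation tests, SIMPER
    decomposition, BIO-ENV/BVSTEP environmental matching and between-matrix
    rank correlation. A seeded synthetic-data generator emulates species trees
    with within-species coalescents, posterior-like tree samples, alignments
    and environmentally driven community tables so that the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    phangorn,
    stats,
    utils,
    vegan,
    withr
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
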