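Package: rcc5align
Title: RCC-5 Concept Alignment of Conflicting Taxonomies and Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Logic-based alignment of conflicting taxonomic and phylogenomic
    concept hierarchies using the five base relations of Region Connection
    Calculus (RCC-5): congruence, proper inclusion, inverse proper inclusion,
    overlap, and exclusion. Input hierarchies are parent/child concept trees
    with per-parent coverage constraints that can be relaxed locally via
    "no coverage" regions; expert articulations between concepts of different
    sources may be disjunctions over the 32-element relation lattice. The
    reasoner checks joint consistency of all constraints, enumerates possible
    worlds, and infers the Maximally Informative Relations (MIR) for every
    cross-source concept pair. Downstream analyses express concept overlap
    under whole- or split-concept resolution, census split-product labels,
    tabulate overlap matrices and clade-name reliability, and annotate rooted
    bipartition concordance/conflict between trees. Includes deterministic
    fixtures reconstructing the neoavian-explosion use case and a seeded
    random problem generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
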