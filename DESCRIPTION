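Package: gnevol
Title: Evolutionary Analysis of Genome Neighbourhoods Around Biosynthetic Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the evolution of plant biosynthetic gene
    clusters through the genome neighbourhoods (GNs) of a target enzyme family
    such as the oxidosqualene cyclases. Extracts fixed-flank gene windows from
    annotated genomes, tests Pfam-style domain enrichment of neighbourhood
    content against the genome background with a one-tailed hypergeometric test
    and a phylogeny-aware conservative correction that collapses monophyletic
    groups of trait-sharing leaves, computes all-vs-all neighbourhood similarity
    (Jaccard index of domain families, Hungarian-matched average amino-acid
    identity, and a copy-penalised domain sequence similarity index), and
    reconstructs ancestral presence/absence of tailoring-enzyme domains on the
    target-gene tree by maximum parsimony with explicit gain/loss event mapping.
    A self-contained simulator generates annotated genomes, domain-hit tables,
    gene trees and binary traits with planted ground truth so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
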