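Package: lecatrace
Title: Ancestral Gene Content Reconstruction by Dollo Parsimony
Version: 0.1.0
Authors@R: person("A.", "Developer", email = "dev@example.org", role = c("aut", "cre"))
Description: Infers the origin (gain node), secondary losses and root-ancestor
    status of gene-family components from binary presence/absence profiles on a
    rooted species or lineage tree, under a single-gain/multiple-loss (Dollo)
    parsimony model. Includes lineage-level categorical summaries of phyletic
    patterns, construction of taxon-occupancy-filtered phylogenomic
    supermatrices from per-gene alignments, a seeded simulator of
    single-gain/multiple-loss gene-content evolution with genome-completeness
    censoring, and a command-line interface wiring the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
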