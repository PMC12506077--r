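Package: phylocurate
Title: Phylogeny-Informed Contamination Removal and Ortholog Curation for Gene Trees
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-driven curation of single-gene phylogenies for taxon-rich
    phylogenomics. Provides an iterative contamination loop that removes
    putative contaminant sequences by their sister relationships in gene
    trees (single sisters, co-contaminant cherry pairs, and clade grabbing
    with non-target allowances), ortholog selection and gap-filled
    supermatrix concatenation with partition maps, composition-based
    sequence curation (silent-site GC content, effective number of codons,
    per-taxon GC-class labelling, similarity and relative-length filters),
    descriptive utilities for designing rules and assessing monophyly
    across curation stages, and a seeded simulator of gene trees with
    planted contaminants for benchmarking. All components key on a
    controlled 10-character taxon-code naming scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
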