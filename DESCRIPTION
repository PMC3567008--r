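Package: cladegap
Title: Target-Species DNA Barcoding Under Incomplete Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying focal species from an incompletely
    sampled genus with multi-locus DNA barcodes. Implements Kimura
    2-parameter and p-distances with explicit missing-data policies,
    neighbor-joining trees with seeded column-bootstrap support,
    alignment summary statistics and simple indel coding, all-species
    and target-specific ("modified") barcode-gap analysis with a PCA
    view of the distance matrix, chloroplast-versus-nuclear gene-tree
    incongruence screening for putative hybrids and misidentified
    vouchers, a two-step clade-then-species identification procedure,
    and a seeded simulator of clade-structured two-genome barcode
    libraries with planted hybrids and mislabels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    graphics,
    phangorn,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
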