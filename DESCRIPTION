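Package: mitorearr
Title: Mitochondrial Gene-Order Rearrangement Analysis for True Bugs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of mitochondrial gene order in
    insects, centred on the heteropteran (true bug) survey workflow: a data
    model for circular, stranded, possibly incomplete gene orders with a
    plain-text grammar and catalog I/O; classification of rearrangement
    events (translocation, duplication, loss, inversion) against the insect
    ancestral gene order; partitioning of rearrangements into three gene
    blocks and six rearrangement units; the family-level rearrangement
    richness statistic; inference of minimal tandem duplication/random loss
    (TDRL) scenarios between gene orders with remnant-site prediction;
    nucleotide composition and strand-skew statistics; and seeded synthetic
    generators for gene orders, catalogs and sequences with known ground
    truth. Ships a transcription of the published heteropteran gene-order
    catalog as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
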