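Package: karyopaint
Title: Comparative Chromosome Painting Analysis and Karyotype Evolution Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-species chromosome painting (Zoo-FISH) data:
    a cytogenetic region-label grammar, validated homology-map containers with
    TSV readers and writers, synteny algebra (fundamental numbers,
    conserved-region counts, syntenic associations, homology-map composition
    to human/ECU segment space, synteny-disruption and plesiomorphy
    inference), binary character matrices with Fitch parsimony and exhaustive
    most-parsimonious-reconstruction enumeration on rooted trees, an
    outgroup-polarized rearrangement placement rule, and a karyotype-evolution
    simulator (Robertsonian fusion/fission, tandem fusion, pericentric
    inversion, whole-arm translocation) with ground-truth painting projections
    and recovery experiments. Ships a packaged comparative painting dataset
    for four phyllostomid bats (Macrotus californicus probes hybridized onto
    three nectar-feeding species).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
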