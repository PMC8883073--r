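Package: introgressr
Title: Diagnostic SNP Markers and Genotype Analytics for Interspecific
    Introgression Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for creating and evaluating interspecific introgression
    lines with diagnostic SNP markers, motivated by the transfer of the
    Brassica rapa A genome into Brassica juncea. Provides a crossing-scheme
    simulator (Haldane meiosis, backcross-self populations with optional
    zygotic selection), subgenome-diagnostic marker selection from parental
    variant tables, marker genotype matrix cleaning and graphical
    genotyping, segregation expectation and distortion statistics,
    sparse-marker to genome-wide genotype projection over a dense SNP
    panel, and identity-by-state distance with neighbor-joining trees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
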