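Package: rnalvr
Title: Length-Variable Regions of Ribosomal RNA: Folding, Consensus
    Structure Models, and Clade Synapomorphy Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of length-variable regions (LVRs,
    also called expansion segments) of 18S and 28S ribosomal RNA. Provides
    pair-maximization folding of short LVR subsequences with canonical and
    wobble pair rules, selection among consensus secondary-structure models by
    a stem-retention (co-variation) criterion, delimitation of LVRs from a
    multiple sequence alignment via per-column gap profiles, transfer of
    reference region annotations onto new sequences by affine-gap global
    alignment, and a scan of named clades for LVR length states that behave as
    molecular synapomorphies. A synthetic-data generator with planted ground
    truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
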