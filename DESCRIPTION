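Package: psimap
Title: Pseudouridine Site Calling and PUS Dependency Mapping from
    Mutational Sequencing of tRNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls pseudouridine sites from chemically induced U-to-C
    mutational sequencing of tRNA and rRNA, using paired treated/control
    per-position base-call counts, motif-specific false-positive-rate
    binomial testing with Benjamini-Hochberg correction, and
    coverage/background filters. Classifies sites as dependent on
    individual pseudouridine synthases from knockout libraries, resolves
    positions in canonical Sprinzl tRNA numbering (including D-loop
    insertions and variable-arm e-positions), derives IUPAC consensus and
    Jensen-Shannon differential motifs around called sites, and profiles
    precursor tRNA modification from leader/intron/trailer-overlapping
    reads. Ships a seeded synthetic-experiment generator with planted
    stoichiometries for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    stats,
    tools,
    utils,
    graphics,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
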