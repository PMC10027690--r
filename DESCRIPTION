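Package: editome
Title: Calling, Annotation and Labeling of Plant Organelle RNA Editing Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing C-to-U and reverse U-to-C RNA editing in
    plant chloroplast and mitochondrial transcriptomes. Edits are called from
    paired DNA and RNA per-position base-count tables with coverage and
    efficiency thresholds, annotated against gene models that may include
    cis- and trans-spliced group I/II introns, and named with a standardized
    label grammar that resolves individual and cumulative amino-acid effects
    of multiple edits within one codon. Includes editome summary statistics
    (location and effect classification, start/stop codon events,
    neighboring-silent-edit detection), a repeat-junction module for
    coverage-stoichiometry and recombination-arrangement reasoning in
    recombining mitogenomes, and a seeded synthetic-data generator so the
    whole pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
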