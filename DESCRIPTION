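Package: dimerscreen
Title: Spacing-Resolved Composite Motif Enrichment and EMSA Cooperativity
    Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to screen open-chromatin region sets for enrichment of
    composite (dimer) transcription-factor motifs at defined half-site
    spacings and orientations, and to quantify DNA-dependent dimerization
    cooperativity from quantified electrophoretic mobility shift assay
    (EMSA) band fractions under an equilibrium two-site statistical-weight
    model. Includes TRANSFAC-format motif parsing, double-strand PWM
    scanning, one-sided exact enrichment tests with conservative Bonferroni
    correction, per-lane and global cooperativity-factor estimators with an
    "infinite omega" reliability rule, homodimer/heterodimer band-fraction
    prediction for protein mixtures, squared-correlation co-expression
    networks, and synthetic-data generators (planted composite motifs,
    noisy titration lane tables, block-correlated expression matrices) so
    the whole pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
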