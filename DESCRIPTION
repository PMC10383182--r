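Package: phospipe
Title: Quantitative iTRAQ Phosphoproteomics of Urinary Extracellular Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a 4-plex iTRAQ quantitative
    phosphoproteomics workflow for urinary extracellular vesicles:
    MGF/FASTA/TSV input-output, peptide mass bookkeeping, target-decoy
    false-discovery-rate filtering of peptide-spectrum matches, collapsing
    to unique phosphopeptides, Mascot-delta-score phosphosite localization,
    reporter-ion extraction with isotope-impurity correction and channel
    normalization, sum-then-ratio peptide quantification, a robust-normal
    error model for log-ratio significance, and differential phosphopeptide
    calling. A fully seeded synthetic-experiment generator (tryptic
    digestion, planted regulation, decoys, positional-isomer competitors,
    reporter noise) makes every stage testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
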