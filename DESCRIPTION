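Package: phycotf
Title: Genome-Wide Transcription Factor Identification and Comparison in Algae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A transcription-factor (TF) identification and classification
    pipeline for predicted algal proteomes. Homology evidence from BLAST
    (tabular), profile-HMM domain scans (per-domain tables) and InterProScan
    annotation is parsed, filtered for false positives, merged per protein
    and classified into TF families through declarative DNA-binding-domain
    (DBD) assignment rules with curation heuristics for MYB repeat classes,
    the SHAQKYF motif, G2-like cross-annotation and copy-number families
    (AP2/ERF, Double B-box). Includes sensitivity/PPV benchmarking against
    gold-standard labels, a comparative layer (count and proportion tables,
    presence/absence dendrograms, proportion-based family clustering,
    MYB-SHAQKYF ratios) and a synthetic evidence generator with planted
    truth labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
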