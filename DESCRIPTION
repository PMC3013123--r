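Package: dnabreathe
Title: Sequence-Dependent DNA Breathing Dynamics with the Extended
    Peyrard-Bishop-Dauxois Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Langevin molecular-dynamics simulation of double-stranded DNA
    "breathing" (spontaneous transient base-pair openings) under the extended
    Peyrard-Bishop-Dauxois (EPBD) mesoscopic model with Morse on-site
    potentials and anharmonic, optionally sequence-dependent stacking.
    Detects bubbles (contiguous runs of base pairs open beyond an amplitude
    threshold) in trajectory ensembles and aggregates them into
    transcription-start-site-anchored average-lifetime and occupancy
    profiles, with tools to contrast the TSS focus of two promoters.
    Also includes comparative-CT (delta-delta-Ct) qPCR fold-change
    arithmetic with two-fold regulation classes, terahertz pulse metadata
    checks, and deterministic synthetic-data generators (promoter sequences,
    planted-bubble trajectories, Ct tables) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
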