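Package: tubulinptm
Title: Tubulin Isotype Proteotyping and C-Terminal PTM Scanning in Populus Xylem
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mass-spectrometry-based proteotyping of plant tubulin
    isotypes and scanning for C-terminal post-translational modifications
    (detyrosination, non-tyrosination, polyglutamylation, Lys-40 acetylation).
    Implements exact monoisotopic mass arithmetic with in silico CNBr and
    trypsin digestion, PTM isoform enumeration and MALDI-TOF peak-list
    scanning with isotopic-envelope validation, label-free relative
    quantification of isotypes from reporter-peptide intensities,
    paralog-aware transcript quantification (FPKM) against hypervariable
    C-terminal reference regions, an iterative bait-based local assembly loop
    for reference correction, and seeded simulators producing reads and
    spectra with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
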