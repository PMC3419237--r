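Package: rnrkit
Title: Simulation and Analysis of Ribonucleotide Reductase EPR, qPCR and
    Sequence Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for characterising class Ia ribonucleotide reductase
    (RNR) small subunits and their expression. Simulates field-swept
    first-derivative powder EPR spectra of S = 1/2 species (tyrosyl radicals
    with anisotropic g and proton hyperfine structure, mixed-valent
    Fe(II)Fe(III) di-iron centres) at X-band and high-field frequencies,
    refines spin-Hamiltonian parameters by least squares, extracts g-values
    from turning points, quantifies spins by double integration against a
    Cu(II)-EDTA standard, and fits first-order radical-decay kinetics.
    Includes efficiency-corrected external-standard qPCR quantification with
    second-derivative-maximum Cp calling and Dunnett many-to-one statistics,
    protein-sequence utilities (translation, pairwise identity, Poisson and
    Kimura distances, neighbor joining with bootstrap supports, KEN-box
    scanning), and seeded synthetic-data generators so every stage can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    tools,
    utils
Suggests:
    multcomp,
    mvtnorm,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
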