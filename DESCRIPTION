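Package: msdesign
Title: Multistate Protein Design on a Bead-Rotamer Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained framework for multistate protein design:
    a genetic algorithm searches sequence space while, for every candidate
    sequence, side-chain rotamers are optimized independently on each of
    several structural states (positive states whose energy should be low,
    negative states whose energy should be high).  Per-state energies are
    combined by a small programmable fitness language with min/max
    operators, binding-energy caps and sequence-constraint terms, which
    makes negative design (binding specificity) expressible.  Rotamer
    packing is performed by a family of algorithms -- BMEC seeding with
    FASTER-style single-residue perturbation/relaxation, a standard
    simulated annealer, a multi-cool annealer, and hybrid
    annealing-plus-relaxation variants with restarts -- backed by a lazily
    computed, memory-capped interaction graph, and checked against an
    exhaustive global-minimum oracle on small instances.  Energies come
    from an exactly specified bead-per-side-chain model (12-6 well,
    hydrophobicity-weighted depth) on synthetic helical scaffolds, so the
    whole design-redock-iterate protocol, including rigid-body redocking
    of undesired complexes and round-by-round binding-energy-error
    tracking, runs at desk scale with no external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
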