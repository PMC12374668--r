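Package: dnatransformr
Title: Design and In-Silico Verification of Nanoparticle DNA-Interface Logic Gates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles Boolean logic gates (YES, NOT, AND, OR, fan-in up to
    four per staple) into nanoparticle DNA-interface architectures built
    from core-receptor, staple and shield-ligand oligonucleotides, designs
    the underlying sequences under hairpin, cross-complementarity, GC and
    homopolymer constraints via seeded rejection sampling, and verifies
    gate behaviour with a domain-level toehold-mediated strand-displacement
    model. Duplex free energies come from a unified nearest-neighbor
    thermodynamic table with entropic temperature rescaling and a
    logarithmic monovalent-salt correction; a restricted hairpin model
    (contiguous stem plus terminal loop) screens designed oligonucleotides.
    Simulation produces truth tables, shield ratios, geometric-mean
    switching thresholds and leakage statistics, with an optional seeded
    stochastic kinetic mode.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    ggplot2,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
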