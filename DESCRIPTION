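Package: tcrpmhc
Title: Structural Analysis of TCR-pMHC Complexes and 1:1 Binding Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural analysis of alpha-beta T-cell receptor
    (TCR) complexes with peptide-MHC (pMHC) class I ligands. Computes docking
    geometry descriptors (crossing angle, incident angle, TCR-center position
    in the pMHC groove frame), per-CDR-loop atomic contact tables and derived
    percentages, solvent-accessible surface areas and buried peptide surface
    by Shrake-Rupley sphere sampling, the Lawrence-Colman shape
    complementarity statistic, Kabsch rigid-body superposition with
    fit-on/measure-on selections and per-residue displacement profiles, and
    simulation plus fitting of 1:1 Langmuir surface plasmon resonance
    binding data. A synthetic-structure generator produces annotated toy
    TCR-pMHC complexes with prescribed docking geometry and contact layouts
    so every analysis is testable without external coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
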