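Package: ffbench
Title: Benchmarking Small-Molecule Force Fields Against Quantum-Chemical Conformer Ensembles
Version: 0.1.0
Authors@R: person("ffbench", "developers", role = c("aut", "cre"), email = "ffbench@example.org")
Description: Tools to benchmark molecular-mechanics force fields against
    quantum-chemical (QM) reference data for conformer ensembles of drug-like
    molecules. Reads V2000 SDF conformer sets with per-record energies, groups
    structures into molecules by canonical labeled-graph identity (tautomers are
    distinct molecules), and quantifies agreement per force field: relative
    conformer-energy differences (ddE) anchored at the lowest-QM-energy
    conformer, matched-conformer mean signed deviations (MSD), symmetry-aware
    minimum RMSD over graph automorphisms, and a normalized torsion fingerprint
    deviation (TFD) in [0,1]. Conformers are paired by a threshold RMSD matching
    procedure with deduplication. A one-sample Z-test for proportions identifies
    force-field parameters overrepresented among molecules with poorly
    reproduced geometries (high TFD). A seeded synthetic-data generator emits
    complete benchmark datasets with known ground truth so every pipeline stage
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
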