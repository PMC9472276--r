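Package: nnlie
Title: End-State Binding Free Energies by Linear Interaction Energy with
    Pluggable Single-Point-Energy Backends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing of end-state molecular dynamics snapshots into
    absolute protein-ligand binding free energies in the linear interaction
    energy (LIE) formalism.  Reads multi-frame PDB trajectories and
    Gromacs-style index (.ndx) groups, extracts protein (P), ligand (L) and
    solvent (S) components, evaluates per-frame single-point energies through
    a uniform calculator contract (a neural-network-potential hook, a pairwise
    dispersion-correction backend with Becke-Johnson or zero damping, and a
    deterministic Lennard-Jones/Coulomb mock for offline testing), forms
    ensemble-averaged interaction energies with convergence diagnostics,
    reduces explicit solvation shells to a distance cutoff, and estimates
    binding free energies with classical and NNP-based LIE equations,
    including coefficient fitting against experimental IC50/Ki values and
    repeated random-split cross-validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
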