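Package: peptriage
Title: Computational Triage of Target-Binding D-Tripeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for the computational stages of a structure-based
    D-tripeptide screening campaign against a protein cavity: grid-based
    pocket detection with a buriedness index and morphological cleanup,
    tripeptide library enumeration and synthesis-set bookkeeping,
    Shrake-Rupley and LCPO solvent-accessible surface areas, NMR-informed
    SASA filtering of docked pose ensembles and per-scoring-function top-pose
    selection, trajectory stability statistics (ligand RMSD, interface RMSD,
    RMSF, center-of-mass bound fraction, residue contact frequencies,
    occupancy grids, average structures), frame clustering with
    Davies-Bouldin, pseudo-F and R-squared quality metrics, single-trajectory
    MM/GBSA-style rescoring with a generalized Born polar term and an
    LCPO-based nonpolar term, in-silico tryptic digestion with crosslink
    delta-mass candidate search, and summaries of SPR kinetic and STD-NMR
    group-epitope-mapping tables. Synthetic-data generators with planted
    ground truth stand in for docking engines and molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
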