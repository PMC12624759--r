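---
title: "Methods: computational triage of cavity-binding D-tripeptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: computational triage of cavity-binding D-tripeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptriage)
```

# The problem this package addresses

Small D-configured tripeptides are attractive starting points for inhibitors
of protein-protein interactions: they are below 500 Da, protease-resistant,
and synthetically trivial. A screening campaign against a target cavity -
here modelled on a 160-residue acidic stress-response protein whose binding
site lies between two flexible acidic loops - proceeds through a chain of
desk computations: find and measure candidate cavities, enumerate the
chemical library, dock against a conformational ensemble, filter poses with
an experimental restraint (STD-NMR says the aromatic side chain is buried),
pick top poses per scoring function, adjudicate them with molecular-dynamics
stability statistics and MM/GBSA-style rescoring, and finally confirm the
binding site by crosslink mass mapping. `peptriage` implements each of those
computational stages as composable, tested functions. Docking engines, MD
integrators and structure predictors are *not* reimplemented: their outputs
enter as annotated inputs, and a synthetic-data module generates all of them
with planted ground truth so every stage can be exercised and verified end
to end.

# Data model

Structures are atom tables (`mol_structure`): serial, name, element, residue,
chain, coordinates in Angstrom, with Bondi-style van der Waals radii assigned
from the element (H 1.20, C 1.70, N 1.55, O 1.52, S 1.80; unknown elements
default to 1.70 with a warning - a convention, since radii rarely appear in
methods sections). Trajectories (`mol_trajectory`) are an atom table plus an
ordered list of coordinate frames; on disk they are multi-model PDB, which is
entirely adequate at the scales synthetic data produces and keeps the package
free of binary trajectory formats. PDB reading and writing delegate to
`bio3d`, with a fixed-width validation pass in front so malformed records are
reported with their line number. Selections are conjunctions of clauses
(`"resid 103-117 and backbone and heavy"`) with closed residue ranges and
1-based residue indexing, as in PDB files.

Superposition is a weighted Kabsch fit (proper rotation enforced via the SVD
determinant correction). Mass weighting uses standard atomic weights; fits
need at least three non-collinear atoms. The test suite cross-checks the
minimal RMSD against an independent quaternion-method oracle and against
`bio3d::fit.xyz`.

# Cavity detection

`find_pockets()` follows the grid/buriedness/morphology recipe used by
pocket-detection tools of the FLAPsite family:

1. **Grid.** The structure is embedded in a lattice (default spacing 1.0 A).
   A voxel is *protein* when its center is within (vdW radius + probe
   radius) of an atom; the default probe of 1.2 A plays the geometric role of
   a small hydrogen probe. The proprietary molecular-interaction-field probe
   the original tool uses is replaced by this purely geometric occupancy -
   a deliberate surrogate that reproduces the probe's shape-carving role
   without an external force field.
2. **Buriedness.** Every remaining voxel is scored by casting rays along 14
   lattice directions (6 axes + 8 corner diagonals; 6 and 26 are also
   available) up to 10 A; the buriedness index is the number of directions
   that hit protein. Voxels below the threshold (default 9 of 14) are
   discarded. The threshold is a convention: published descriptions say only
   that points "below a specific threshold" are discarded, so the value is
   exposed as a parameter rather than hard-coded.
3. **Morphology.** One binary erosion then one dilation (an opening) with the
   6-connected structuring element removes voxel-scale noise. We threshold
   first and then apply morphology; the original description orders the
   steps ambiguously, and opening after thresholding is the variant that is
   idempotent on clean input.
4. **Labeling.** 6-connected components become pockets; volume is voxel
   count x spacing^3; components under 30 A^3 are suppressed as noise.
   Lining residues are those with an atom within (vdW + probe + spacing) of
   a pocket voxel. Ranking combines normalised volume with a hydrophobic
   score - the fraction of lining residues in {A,V,L,I,M,F,W,P} - which is a
   residue-class surrogate for a hydrophobic-probe field and documented as
   non-equivalent to it.

On the planted spherical cavity (radius 4 A, ideal volume 268.1 A^3) the
pipeline reports a single pocket of 256 A^3 at 1 A spacing, a 4.5%
discretisation error that shrinks monotonically as the grid is refined
(2.0 to 1.0 to 0.5 A), and a convex control body yields no pockets.

# The tripeptide library and its bookkeeping

The library is all sequences over the 19-letter alphabet (20 standard amino
acids minus cysteine, which is excluded to avoid disulfide chemistry), as
C-terminal amides with free N-termini: 19^3 = 6859 tripeptides. D
configuration is metadata only - monoisotopic mass and charge are
stereochemistry-independent and nothing in scope consumes 3D chirality.
Synthesis-set selection concatenates the top k per cavity (k = 8 over four
cavities gives the 32-peptide synthesis set; k = 25 the 100-peptide
investigation set), retaining and flagging duplicates. The net-charge
descriptor is a deliberate integer heuristic (+1 free N-terminus, +1 per
R/K, 0.1 per H rounded, -1 per D/E, -1 free acid C-terminus), not a
Henderson-Hasselbalch titration.

# Solvent accessibility

`shrake_rupley()` places a deterministic golden-section spiral of test points
(default 960, at least 96) on each atom's solvent-expanded sphere; the
exposed fraction times the sphere area is the atom's SASA. Determinism was
chosen over random sampling for bit-reproducibility; at 960 points the total
over random 50-atom clusters is within 2% of a 4000-point reference and
rotation-invariant to better than 0.5%. Hydrogens are excluded by default
(united-atom convention, matching the LCPO usage). Side-chain SASA is the sum
over the residue's non-backbone heavy atoms, so glycine reports exactly zero.

`lcpo_sasa()` implements the linear-combination-of-pairwise-overlaps
approximation used for the nonpolar solvation term: per atom,
`P1*S1 + P2*sum A_ij + P3*sum A_jk + P4*sum A_ij sum A_jk`, where `A_ij` is
the lateral area of sphere i buried inside neighbour j. Topologies carry the
coefficients explicitly. For the nonbonded bead atoms of the synthetic
systems the defaults are P = (1, -1, 0, 0), which is *exact* for isolated
and pairwise-overlapping spheres; fitted protein parameter tables are out of
scope because every in-scope topology supplies its own coefficients.

# Pose triage

The experimental restraint enters here: saturation-transfer-difference NMR
shows the aromatic side chain (Tyr or Trp) of the best binders is buried on
binding, so docked poses whose aromatic side-chain SASA exceeds 20 A^2 are
excluded. The boundary is excluded-if-strictly-greater - a pose at exactly
20 A^2 is retained - matching the stated exclusion rule; a `strict_less`
flag flips it. The filter emits a complete audit table (every pose appears
exactly once with its measured value and decision). Probe radius and point
count are recorded in the result since the upstream engine's SASA settings
are unknown; equivalence is claimed only at the level of the 20 A^2 decision
boundary.

From the survivors, `select_top_poses()` picks pose #1 (minimum Vina-like
score), pose #2 (maximum CNN pose score, a 0-1 quantity) and pose #3
(maximum CNN affinity). No consensus ranking is computed - the three
scoring functions are kept as independent adjudicators. Ties are broken by
lexicographic pose id and logged; the upstream tools' tie behaviour is
unstated, so this is an artifact convention.

# Trajectory statistics

* **Ligand RMSD**: each frame is superposed on a receptor-only selection
  (typically C-alpha atoms in secondary structure) and the ligand RMSD to the
  reference is computed with no further fitting, so genuine ligand motion is
  not absorbed by the fit. A secondary-structure mask can be supplied
  explicitly; a simple phi/psi-window assignment is a documented fallback
  since no DSSP reimplementation is in scope.
* **Interface RMSD** (CAPRI convention): interface residues are those of
  either partner with a heavy atom within 10 A of the other partner in the
  reference; the model is fitted on the interface backbone and scored on it.
  An empty interface is reported as undefined with a diagnostic, never as a
  silent zero.
* **RMSF**: per-atom fluctuation about the time-averaged position after
  fitting, aggregated per residue with mass weights.
* **Bound fraction**: per frame, the distance between the peptide center of
  mass (mass-weighted heavy atoms) and the site center of mass (C-alpha atoms
  only, matching the described site-COM convention); frames above 6 A are
  unbound. The site itself is captured at 5 A from the reference peptide
  pose and frozen thereafter. The source protocol quotes both 5 A (site
  capture) and 6 A (unbound cutoff); both are parameters here with those
  defaults. Whether the peptide COM was mass-weighted upstream is unstated;
  mass-weighted is the default and the generator's separability condition
  makes the recovered fraction insensitive to that choice.
* **Contacts**: hydrogen bond (donor-acceptor heavy atoms at 3.5 A or less,
  with a D-H...A angle of at least 120 degrees when hydrogens are present,
  distance-only otherwise), salt bridge (Arg/Lys/His nitrogen to Asp/Glu
  oxygen at 4.0 A or less), van der Waals (heavy-atom distance within
  r_i + r_j + 0.5 A across residues), cation-pi (charged nitrogen within
  6.0 A of the aromatic ring centroid and within 60 degrees of the ring
  normal). These geometric conventions follow common contact-analysis
  tooling; the exact upstream thresholds are unstated, so all are
  configurable in `contact_spec()`. Pairs at or below 25% frequency are
  dropped from the filtered view; the full table is always retained as the
  audit.
* **Occupancy grids** (default 0.5 A voxels) and mass-weighted-fit average
  structures complete the set.

# Ensemble clustering

Frames are superposed once onto the first frame over the clustering
selection and the selected coordinates are flattened, so Euclidean feature
distance equals sqrt(n_sel) times the selection RMSD under a single global
fit. This matches the convention of mainstream trajectory-clustering tools
and is documented as an approximation to true pairwise-fit RMSD. K-means
(via `stats::kmeans`, multi-start, seeded - the standard R implementation
rather than a hand-rolled Lloyd loop; k = n is handled directly as the
zero-SSE optimum) and average-linkage hierarchical clustering with an RMSD
tree cut (default 2.5 A) are both provided, with k = 10 the ensemble-docking
default. Quality metrics: Davies-Bouldin index (within-cluster scatter =
mean distance to centroid), pseudo-F in the Calinski-Harabasz form
((SST-SSE)/(k-1)) / (SSE/(n-k)) - the precise normalisation used upstream is
unstated, so this standard form is adopted - and R-squared = 1 - SSE/SST.
Representatives are the frames nearest their centroids; population ties take
the lowest cluster id.

# MM/GBSA-style rescoring

Single-trajectory convention: complex, receptor and ligand are evaluated on
the same frame, so intramolecular molecular-mechanics terms cancel and the MM
part reduces to intermolecular Coulomb (332.0637 q_i q_j / r, no cutoff) and
12-6 Lennard-Jones with Lorentz-Berthelot combination. Polar solvation is
generalized Born: effective radii from the pairwise-descreening integral
with OBC-style rescaling (alpha 1.0, beta 0.8, gamma 4.85 - the GB variant
used upstream is unstated, and this is the common modern default), and
`G = -166.0319 (1/eps_in - 1/eps_solv) sum q_i q_j / f_GB` with the standard
exponential interpolation for `f_GB`, self terms included. The dielectric
offset is 0 rather than the 0.09 A some codes use, so an isolated ion's
effective radius equals its intrinsic radius and the Born closed form is
recovered exactly - a clean, testable limit. No salt term (zero ionic
strength). The nonpolar term is `gamma * SASA_LCPO + beta` per species with
gamma = 0.0072 kcal/mol/A^2 and beta = 0. The solute entropy is deliberately
omitted, so totals are *relative* binding energies; trajectory averaging
reports the mean decomposition and the SEM over frames.

Absolute values from this machinery are not comparable to published numbers
computed on microsecond explicit-solvent trajectories with full force
fields; what is in scope - and tested - is the machinery itself: closed-form
limits, rigid-motion invariance, a vanishing dG in the non-interacting
limit, and correct rank ordering of a planted strong binder against a decoy
in at least 19 of 20 seeded systems.

# Crosslink mass mapping

Tryptic digestion cleaves C-terminal to K and R, skips cuts before proline,
and enumerates fragments with per-residue missed-cleavage caps (K at most 3,
R at most 2) applied jointly with a global cap of 3 - mirroring the stated
search settings. Monoisotopic masses are sums of standard residue masses
plus water, minus 0.984016 amu for C-terminal amides; carbamidomethyl
cysteine (+57.02146) is a default fixed modification and single methionine
oxidation (+15.99491) the default variable one. m/z uses the
*hydrogen-atom* mass (1.007825) per charge rather than the bare proton
(1.007276): the hydrogen convention reproduces the campaign's printed
calculated m/z of 820.4351 from 2458.2821 to under 1 ppm, the proton
convention does not (820.4346), and the convention is a parameter. The
crosslink search adds a given mass shift (the diazirine-tripeptide remnant,
+574.3229 amu here) to every fragment/modification state and matches
calculated against observed m/z within a ppm tolerance (default 10),
site-agnostically - the published identification is mass-level, and
fragment-ion (MS2) scoring is out of scope.

# Experiment-table summaries

SPR kinetics tables are summarised by plain arithmetic means of the printed
per-concentration fits; a diagnostic flags rows where kd/ka disagrees with
the reported KD by more than 10%. One of the two shipped example tables has
an average row inconsistent with its own columns and a dissociation rate two
orders below its siblings; the package flags such rows and deliberately does
not "correct" them - printed data are inputs, not quantities to repair. STD
group epitope mapping normalises proton integrals to the strongest proton,
which is set to exactly 100% (all tied maxima report 100).

# The synthetic-data module

Every generator is a pure function of its arguments including the seed, and
every planted value is re-derivable from the emitted structures - both
properties are tested.

* **Cavity protein**: three concentric Fibonacci-lattice shells of dummy
  carbons around an empty sphere, with a mouth channel narrower than the
  probe seal so the grid sees a closed cavity; the generator flood-fills its
  own output and refuses parameters that leave the shell open. Manifest:
  the analytic volume 4/3 pi r^3, center, mouth direction.
* **Binding trajectory**: a frozen six-residue toy receptor (site COM at the
  origin by symmetry) plus a rigid Arg-Tyr-Arg peptide whose COM sits at the
  bound (4 A) or unbound (9 A) distance per the requested mask, with
  isotropic Gaussian jitter (default sigma 0.2 A). The generator enforces
  the separability condition bound + 3 sigma < 6 < unbound - 3 sigma, so the
  recovered bound fraction equals the planted one exactly. Three contacts
  are planted to hold in exactly the bound frames - an Arg-Glu salt bridge
  (2.6 A), a hydrogen-bond geometry (2.7 A) and a Lys/Tyr-ring cation-pi
  stack (3.5 A along the ring normal) - all positioned on the far side of
  the unbinding direction so displacement breaks them with margin well
  beyond the jitter.
* **Pose set**: a Gly-Tyr-Gly peptide whose tyrosine ring is clamped between
  two dense receptor slabs; the slab gap is bisected per pose until the
  measured side-chain SASA is within 2 A^2 of the requested value, giving
  direct control of the filter feature. Requests outside the feasible range
  are refused with that range.
* **Energy system**: a rigid host with one negative and one positive
  triangular site 20 A apart and a positive guest triad docked at either
  site; the strong/decoy ordering is planted purely by geometry under a
  single shared topology, and flipping the guest charge inverts it.

What the generators do *not* emulate: real protein packing and secondary
structure, solvent, force-field energetics, conformational flexibility of
the ligand, correlated noise in trajectories, and score distributions of
real docking engines. Passing tests therefore demonstrate that the
*statistics and algorithms* are implemented correctly and recover planted
truth under controlled conditions - they say nothing about re-deriving any
particular published simulation value, which would require the original
trajectories and engines.

# Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately small scales
chosen as the package's own defaults for synthetic verification: cavity
shells of ~1900 atoms on ~40^3-voxel grids, trajectories of 50-100 frames
(9 planted fractions x 20 seeds for the recovery property), pose ensembles
of 4 poses with 960-point SASA, 13-atom energy systems over 20 seeds, and
80-frame two-blob clustering problems. Degenerate inputs fail loudly:
fewer than three or collinear fit atoms, empty selections, ragged MODEL
blocks, overlapping atoms in energy evaluation, zero STD integrals, and
empty interfaces all raise informative errors rather than returning
placeholder values.

# Known limitations

* Pocket volumes are voxel counts, not alpha-shape volumes; agreement with
  alpha-shape tools is expected only at the level of pocket presence and
  approximate size.
* The hydrophobic pocket score is a residue-class fraction, not an energy
  field.
* LCPO with the neutral bead coefficients is exact only through pairwise
  overlaps; dense clusters need fitted coefficient tables supplied via the
  topology.
* GB omits salt, and the single global-fit RMSD used for clustering is an
  approximation to pairwise-fit RMSD.
* Multi-model PDB is the only trajectory format; binary formats are out of
  scope.
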