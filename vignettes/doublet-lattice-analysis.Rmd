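---
title: "Analysing the doublet microtubule lattice: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing the doublet microtubule lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doubletlattice)
```

## The system and the questions

The ciliary doublet microtubule is built from a complete 13-protofilament
(PF) A-tubule and an incomplete 10-PF B-tubule that attaches to the A-tubule
exterior. Three structural questions drive this package:

1. **Lattice geometry.** How much does each adjacent PF pair rotate about the
   tubule axis, and what "theoretical PF number" (360° divided by the
   rotation angle) does that local curvature correspond to? Where is the
   lattice seam — the unique lateral contact where an alpha subunit meets a
   beta subunit instead of its own kind?
2. **Outer-junction energetics.** How strong are the non-canonical lateral
   contacts that tether PF-B1 to PFs-A10/A11 (buried surface area, salt
   bridges), and why does the B-tubule bind exactly there? The package
   rebuilds the hypothetical-junction experiment: graft the A10 dimer and the
   rigid A11/B1 complex onto every other A-tubule pair and score each graft
   for clashes and bridge formation.
3. **Density-level evidence.** Simulated model density supports voxel-size
   calibration, difference mapping that exposes microtubule inner proteins
   (MIPs), PF subvolume averaging, and the 4-nm-shift cross-correlation test
   that fixes the alpha/beta register of each PF.

A companion conservation module contrasts per-residue tubulin conservation
between ciliated and non-ciliated organisms over the eight lattice regions
contacted by filamentous MIPs.

## The synthetic lattice generator

Every stage is testable without external data through `lattice_spec()`,
`build_singlet()` and `build_doublet()`. The generator's defaults are the
canonical study conditions, not tuning knobs:

* **dimer rise 80 Å** (8-nm repeat; the real ~81.6 Å repeat is configurable),
  monomer rise 40 Å, beta below alpha within each dimer so the beta-to-alpha
  direction defines "plus end up";
* **twist 360/n_pf degrees** per PF (27.692° for 13 PFs);
* **B-lattice stagger 3·40/n_pf ≈ 9.231 Å** per PF — the 3-start monomer
  helix. Around 13 PFs the accumulated stagger is 120 Å ≡ 3 monomer rises,
  an odd multiple of 40 Å, which is exactly what creates the single seam at
  the wrap-around contact. The accumulated stagger is wrapped into one dimer
  rise per PF so a built segment is cut perpendicular to the axis rather than
  sheared;
* **radius 110 Å**, giving the ~53 Å centre-to-centre lateral PF spacing of a
  13-PF wall; **2 dimer repeats** per PF;
* a **50-pseudo-atom monomer template** (`template_monomer()`): a
  deterministic asymmetric random cloud, with distinct alpha and beta shapes.
  Asymmetry is what makes rotation recovery and register assignment
  well-posed; the template is *not* a biophysically realistic tubulin (no
  secondary structure, no real side chains), so interface scores on synthetic
  lattices are comparators only.

The doublet builder grafts a 10-PF open arc outside the A-tubule between two
designated PFs (default 10 and 11), with the arc winding in the same
rotational sense as the A numbering so that the far end (B10) lands on the
inner-junction side. Ground truth — per-chain tubule, PF, dimer and
alpha/beta identity — is recorded on the model and used by the test-suite to
score every downstream stage.

What passing tests on these lattices do **not** show: robustness to missing
density, radiation damage, flexible M-loops, or non-ideal PF packing in real
cryo-EM maps. They do show that the geometric and numerical machinery is
exact on known ground truth.

```{r generator}
doublet <- build_doublet()
assignment <- assign_pfs(doublet)
assignment
```

## Axis estimation and the twist decomposition

All rotation angles are referred to the microtubule longitudinal axis. For an
8-nm repeat the structure is an oblate ring (diameter ~500 Å versus height
~160 Å), so the largest-variance principal axis is *perpendicular* to the
tubule — a pitfall for the obvious PCA estimate. `estimate_axis()` instead
uses the lattice's stacking structure: each chain's nearest neighbouring
chain is its intradimer partner 40 Å away along the axis (closer than the
~53 Å lateral spacing), so the sign-aligned mean of nearest-neighbour
displacement vectors lies along the axis, exactly so for ideal lattices. Two
guards keep this honest: displacements that are not axial (possible for very
low-curvature pairs, where lateral neighbours come within 40 Å) are discarded
by an inlier loop, and a cloud whose displacements have no consistent
direction is rejected as axis-free.

`twist_about_axis()` performs the twist–swing decomposition via quaternions:
the twist of rotation `R` about unit axis `n` is `2·atan2(v·n, w)` for the
quaternion `(w, v)` of `R`. The axial shift is the displacement of a point on
the axis projected onto `n`, and the axis deviation (angle between the
transform's own rotation axis and the lattice axis, folded to 0–90°) is
reported rather than enforced; pairs with deviation above 20° are flagged
unreliable instead of silently re-fitted. Rotations below 1e-6° are reported
as twist 0 with a `degenerate` flag.

Per-pair geometry superposes one dimer of each PF (Kabsch, proper rotation
guaranteed via the SVD determinant correction) on equivalent atoms matched by
subunit rank and atom identity. `pf_class` rounds the theoretical PF number
half away from zero.

```{r geometry}
report <- lattice_report(doublet, assignment)
head(report[, c("pf_i", "pf_j", "angle_deg", "z_shift", "pf_class", "register")])
attr(report, "summary")
```

## Protofilament assignment

`assign_pfs()` works in the plane perpendicular to the axis: a deterministic
RANSAC circle fit locks onto the dominant (complete) ring to split A- from
B-tubule chains (relaxed by nearest-circle reassignment), then chains cluster
into PFs by azimuth about each tubule's own fitted centre. The number of PFs
is chosen where the sorted circular gap sizes drop fastest in *ratio* — a
rule that tolerates both a closed ring (13 equal boundary gaps) and an open
arc (one huge mouth gap plus 9 boundary gaps). A tubule is "open" when its
largest PF-to-PF gap exceeds 1.7 times the median gap. Doublet labels are
anchored at the outer junction: B1 is the arc end nearest the A-tubule, its
two nearest A PFs become A10/A11, and of the two possible numbering
directions the one that brings A1 closest to B10 (the inner junction) wins.

Seam classification follows the lateral-neighbour rule: for each alpha
subunit the nearest chain of the adjacent PF (by axial offset) votes "seam"
if it is a beta subunit. Only subunits with a clear lateral partner (axial
offset ≤ 10 Å, a quarter monomer rise) vote, which keeps the cut ends of a
finite segment from corrupting the call.

## Interface analysis

* **SASA** (`compute_sasa()`): Shrake–Rupley with a deterministic
  golden-spiral point set (default 960 points, probe 1.4 Å), cell-list
  accelerated in C++. Hydrogens are excluded by default (deposited tubulin
  models are heavy-atom). A sphere point exactly on a neighbour's surface is
  buried only for the higher-index atom, so coincident spheres count their
  shared surface once.
* **Buried surface area** (`buried_surface_area()`):
  `SASA(A) + SASA(B) − SASA(A∪B)`, the full-sum convention, with the halved
  (per-side) value reported alongside — published tables use either, so the
  reproduction test accepts whichever matches.
* **Salt bridges** (`detect_salt_bridges()`): donor heavy atoms Arg
  NH1/NH2/NE, Lys NZ, His ND1/NE2 (histidine assumed protonated — required
  for the known B1–A11 histidine bridge) against acceptors Asp OD1/OD2, Glu
  OE1/OE2 and C-terminal OXT at a 4.0 Å cutoff, deduplicated to one record
  per residue pair keeping the minimum distance.
* **Clashes** (`count_clashes()`): van der Waals overlap > 0.4 Å, a common
  severe-clash criterion.
* **Nonbonded score** (`nonbonded_score()`): electrostatics with formal ±1
  charges on charged-group centroids and the shift damping
  `(1 − (r/r_c)²)²` that vanishes exactly at the 8.5 Å cutoff; Lennard-Jones
  by element with a cubic switching function between 6.5 and 8.5 Å. The
  parameters are a coarse bundled table: the score is a *comparator*
  (stronger/weaker), in arbitrary units, not an energy in kcal/mol.

## Hypothetical outer junctions

`extract_junction_templates()` takes the A10 dimer and the rigid A11/B1
two-dimer complex from a doublet. `build_hypothetical_junction()` grafts the
A10 template onto one host PF and the complex onto the adjacent host using
only the A11-region CA-level atoms for the fit, carrying B1 along rigidly
(internal distances preserved to 1e-9 Å). `score_junction()` evaluates the
grafted A10–B1 contact: any clash → `"clash"`; no clash but no salt bridge →
`"no-bridge-gap"`; otherwise `"compatible"`. The thresholds are shared with
the interface module. On a uniform synthetic lattice every non-seam host pair
scores identically (the seam pair differs genuinely: its axial register is
shifted by one monomer), which is the symmetry test of the scan.

```{r junction}
scan <- junction_scan(doublet, assignment)
scan[scan$native, ]
```

## Density tools

* **Simulation** (`simulate_density()`): each atom is an isotropic Gaussian
  with `sigma = resolution/(π√2)` — a standard real-space rendering width —
  weighted by atomic number and truncated at 4 sigma (0.02% mass loss);
  values are scaled so the plain voxel sum equals the total weight. An
  independent untruncated renderer in the test-suite guards the convention.
* **Difference maps** (`difference_map()`): the simulated map is
  affine-scaled (gain + offset) to the experimental map over the *model
  footprint only* (simulated density above 5% of its maximum), so MIP
  densities do not bias the fit, then subtracted. The scaling protocol for
  the published subtractions is not documented; affine-over-footprint is this
  package's stated assumption.
* **Voxel-size calibration** (`calibrate_voxel_size()`): scan of ±3% in 0.1%
  steps; at each scale the grid geometry is reinterpreted (voxel and origin
  scale together) and the model re-simulated on it, so no interpolation
  enters; a parabolic refinement of the correlation peak gives sub-step
  accuracy (±0.002 Å in the mislabel test, mirroring a 1.395 → 1.375 Å
  correction).
* **Register assignment** (`assign_alpha_beta_register()`): per PF, the
  fitted dimer's simulated density is correlated with the map at register 0
  and shifted +40 Å (one monomer: the alpha/beta swap) along the axis, within
  the union footprint mask; the larger correlation wins and
  `|cc0 − cc4|` is the confidence. A symmetric (alpha = beta) template makes
  the test undecidable and is flagged ambiguous — asymmetry of the real
  density is precisely what the published 4-nm-shift test exploits.
* **Subvolumes** (`extract_subvolumes()`, `average_subvolumes()`): trilinear
  resampling into a common frame through each dimer's rigid transform; no
  missing-wedge weighting. Optional local refinement does coordinate-wise 1-D
  searches (±3 voxels translation, ±5° rotation, parabolic sub-step) against
  the running average and keeps a refined pose only when it improves the
  correlation, since resampling smooths a volume and a null adjustment must
  not degrade already-aligned members.

No resolution estimation (FSC) is performed anywhere: published resolutions
are accepted as map metadata.

## Conservation module

`conservation_profile()` scores each alignment column per group with the
normalised Shannon-entropy complement `1 − H/log 20` (gaps excluded from the
frequencies; all-gap columns are undefined rather than 0; columns > 50% gaps
are flagged). The published analysis names no conservation metric, so a
fraction-identity alternative is provided behind `metric = "identity"` for
sensitivity checks. `region_report()` maps the eight bundled fMIP-contact
regions (four per tubulin; `tubulin_regions()`) onto the alignment through
the reference sequence and *verifies the expected subsequence*, failing
loudly on numbering drift. One bundled region is published with an
end-coordinate one residue beyond its 10-residue subsequence; the subsequence
is treated as authoritative (end 371). No taxon database ships with the
package: group labels are user input. `export_scores_to_structure()` writes
scores into B-factors (scaled 0–100) for surface colouring.

## Problem sizes, tolerances and degenerate inputs

The test-suite and acceptance script run entirely on synthetic data at desk
scale: doublets of 13+10 PFs × 2 dimers (4,600 pseudo-atoms), density grids
at 4 Å voxels (~0.4 M voxels), register assignment over 20 noise seeds,
subvolume statistics over 50 seeds. Key numerical choices:

* superposition requires ≥3 non-collinear paired atoms; collinear sets error;
* twist decomposition treats rotations < 1e-6° as degenerate (twist 0,
  flagged);
* PF clustering errors out when no angular gap exceeds 2°, rather than
  guessing;
* BSA is clipped at zero with a warning only below −1 Å²;
* structure round-trips are exact to the 0.001 Å precision of the PDB/mmCIF
  fixed-point format; map round-trips to float32;
* unknown elements fall back to carbon's 1.70 Å radius with a warning;
  hydrogens are excluded from SASA/clash analysis by default.

## Known limitations

* The pseudo-tubulin template carries no chemistry: salt-bridge and
  nonbonded scores are only meaningful on real coordinate models.
* Analyses of deposited models need a local copy of the coordinates (e.g.
  the 8-nm doublet entry 5UBQ for `reproduce_doublet_analysis()`); nothing
  is downloaded.
* PF identity is always derived geometrically, never read from chain
  identifiers, because deposited chain naming conventions vary.
* The hypothetical-junction scan scores rigid grafts; no relaxation of the
  grafted models is attempted, so verdicts near the clash threshold should
  be read qualitatively.
* Signed twist follows the package's convention (positive =
  counterclockwise viewed from the plus end); published tables report
  magnitudes only, and `pf_class` uses magnitudes.
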