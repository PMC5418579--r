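# doubletlattice

Structural analysis of the ciliary **doublet microtubule** tubulin lattice in
R: protofilament (PF) geometry, outer-junction interface energetics,
model-based cryo-EM density tools, and ciliated-versus-non-ciliated tubulin
conservation profiling — with a synthetic lattice generator so the whole
pipeline runs and is tested without any external data.

## Who this is for

Structural biologists and methods developers working with microtubule or
axoneme models and maps who want reproducible, scriptable versions of the
analyses usually done interactively in molecular viewers: measuring inter-PF
rotation angles, locating the lattice seam, quantifying lateral tubulin
interfaces, building hypothetical junction models, subtracting model density
from maps to expose microtubule inner proteins (MIPs), and assigning the
alpha/beta register of each PF.

## The quantities at the core

For adjacent protofilaments *i, j*, the rigid transform taking one fitted
dimer onto the other is decomposed about the tubule axis **n** (twist–swing,
via quaternions):

- rotation angle θ<sub>ij</sub> = twist about **n**; axial shift
  Δz<sub>ij</sub>; deviation of the transform's own rotation axis from **n**
  (flagged above 20°);
- **theoretical PF number** = 360° / |θ<sub>ij</sub>|, the PF count of an
  ideal microtubule with that local curvature, rounded to the nearest
  integer as `pf_class`;
- **seam**: the lateral contact where an alpha subunit's nearest neighbour in
  the adjacent PF is a beta subunit (vs. the B-lattice alpha–alpha register
  with its ~9.2 Å stagger).

Interfaces are quantified by buried surface area
BSA = SASA(A) + SASA(B) − SASA(A∪B) (Shrake–Rupley SASA, probe 1.4 Å, 960
deterministic sphere points), salt bridges (donor–acceptor heavy atoms ≤
4.0 Å), steric clashes (vdW overlap > 0.4 Å) and a cutoff nonbonded score
(shifted Coulomb + switched Lennard-Jones, 6.5–8.5 Å, arbitrary units).

Density tools render atoms as Gaussians with σ = resolution/(π√2), compute
affine-scaled difference maps over the model footprint, calibrate voxel
sizes by correlation scanning, extract and average PF subvolumes, and assign
each PF's alpha/beta register by comparing the map correlation of the fitted
dimer at its position versus shifted +4 nm along the axis.

## Worked example

```r
library(doubletlattice)

doublet    <- build_doublet()          # ideal 13 + 10 doublet, ground truth attached
assignment <- assign_pfs(doublet)
assignment
#> tubule A: 13 PFs (closed), 52 chains
#> tubule B: 10 PFs (open), 40 chains

report <- lattice_report(doublet, assignment)
head(report[, c("pf_i","pf_j","angle_deg","z_shift","pf_class","register")], 4)
#>   pf_i pf_j angle_deg  z_shift pf_class  register
#> 1   A8   A9  27.69231 9.230769       13 B-lattice
#> 2   A9  A10  27.69231 9.230769       13 B-lattice
#> 3  A10  A11  27.69231 9.230769       13 B-lattice
#> 4  A11  A12  27.69231 9.230769       13 B-lattice
```

Every adjacent pair of the ideal 13-PF A-tubule rotates by 360/13 = 27.692°
(`pf_class` 13) with the 9.231 Å B-lattice stagger; exactly one pair in the
closed A-tubule is classified `seam`. Real doublet models give heterogeneous
angles — that heterogeneity is the local-curvature signal the junction scan
builds on.

```r
emap <- simulate_density(doublet, resolution = 20, voxel_size = 4)
reg  <- assign_alpha_beta_register(emap, doublet, assignment, resolution = 20)
head(reg, 3)
#>   pf       cc0       cc4   register confidence ambiguous
#> 1 A1 0.6554869 0.2237750 register-0  0.4317119     FALSE
#> 2 A2 0.6510430 0.2185498 register-0  0.4324933     FALSE
#> 3 A3 0.6576694 0.2311170 register-0  0.4265524     FALSE
sum(reg$register == "register-0")   # 23 of 23 PFs at the true register
#> [1] 23
```

`cc0` / `cc4` are the map correlations of each PF's dimer at the fitted
position and shifted one monomer (+4 nm); the fitted register wins for all
23 PFs, with the margin (`confidence`) reflecting how distinguishable the
alpha and beta shapes are.

For a deposited doublet model (local file):

```r
res <- reproduce_doublet_analysis("5ubq.cif")
res$report          # per-pair angles and classes for both tubules
res$junction        # the six outer-junction interfaces (BSA, bridges, scores)
res$scan            # clash / no-bridge-gap / compatible verdict per host pair
```

A thin command-line wrapper ships in `inst/cli/doubletlattice.R`
(subcommands `simulate`, `geometry`, `junction-scan`, `diffmap`, `conserve`,
`reproduce-doublet`).

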