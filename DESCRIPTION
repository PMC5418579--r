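Package: doubletlattice
Title: Geometry, Interfaces and Density Analysis of the Ciliary Doublet Microtubule Lattice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the protofilament lattice of the ciliary doublet
    microtubule from atomic models and cryo-EM density maps: rigid-body superposition
    with twist-swing decomposition of inter-protofilament rotations, theoretical
    protofilament-number classification, seam and B-lattice register detection,
    buried-surface-area / salt-bridge / steric-clash / cutoff nonbonded scoring of
    lateral tubulin interfaces, hypothetical outer-junction model building and
    scanning, model-based density simulation, voxel-size calibration, difference
    mapping, protofilament subvolume extraction and averaging, 4-nm-shift
    alpha/beta register assignment by cross-correlation, and ciliated versus
    non-ciliated tubulin conservation profiling. Includes a synthetic lattice and
    density generator with recorded ground truth so every stage can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    seqinr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
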