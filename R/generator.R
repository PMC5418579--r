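#' Specification of an ideal tubulin lattice
#'
#' Defaults reproduce the canonical 13-PF, single-seam B-lattice with the 8-nm
#' dimer repeat used throughout the package: dimer rise 80 A (monomer rise
#' 40 A), inter-PF twist 360/n_pf degrees, and a 3-start monomer-helix stagger
#' of 3 * 40 / n_pf A per PF. A closed lattice requires `stagger * n_pf` to be
#' an integer multiple of the monomer rise; otherwise set `open_arc`.
#'
#' @param n_pf number of protofilaments of the full circle (>= 2)
#' @param dimer_rise axial dimer repeat, A (default 80)
#' @param twist_deg rotation per PF, degrees (default 360 / n_pf)
#' @param stagger axial shift per PF, A (default 3 * dimer_rise / 2 / n_pf)
#' @param radius axis-to-monomer-centre radius, A (default 110, the scale of a
#'   13-PF microtubule wall)
#' @param n_repeats number of stacked dimers per PF (default 2)
#' @param open_arc number of PFs actually built for an incomplete tubule
#'   (NULL = closed)
#' @param seed integer seed controlling the pseudo-monomer template jitter
#' @return object of class `lattice_spec`
#' @export
lattice_spec <- function(n_pf = 13, dimer_rise = 80, twist_deg = 360 / n_pf,
                         stagger = 3 * (dimer_rise / 2) / n_pf, radius = 110,
                         n_repeats = 2, open_arc = NULL, seed = 1) {
  stopifnot(n_pf >= 2, dimer_rise > 0, radius > 0, n_repeats >= 1)
  if (!is.null(open_arc)) stopifnot(open_arc >= 0, open_arc <= n_pf)
  structure(list(n_pf = n_pf, dimer_rise = dimer_rise,
                 monomer_rise = dimer_rise / 2, twist_deg = twist_deg,
                 stagger = stagger, radius = radius, n_repeats = n_repeats,
                 open_arc = open_arc, seed = seed),
            class = "lattice_spec")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Pseudo-tubulin monomer template
#'
#' A coarse 50-pseudo-atom asymmetric blob standing in for a tubulin monomer,
#' so tests and demonstrations need no external coordinates. The alpha and
#' beta templates are distinct random clouds (deterministic given `seed`), so
#' rotation recovery and alpha/beta register assignment are well posed. Atoms
#' are named CA with residue numbers 1..n so equivalent-atom pairing works
#' across copies.
#'
#' @param subunit "alpha" or "beta"
#' @param n_atoms number of pseudo-atoms (default 50)
#' @param size approximate half-extent of the blob, A (default 16)
#' @param seed integer
#' @return structure_model of one chain "T"
#' @export
template_monomer <- function(subunit = c("alpha", "beta"), n_atoms = 50,
                             size = 16, seed = 1) {
  subunit <- match.arg(subunit)
  off <- if (subunit == "alpha") 0 else 10000
  xyz <- with_seed(seed + off, {
    m <- matrix(stats::runif(n_atoms * 3, -size, size), ncol = 3)
    m[, 3] <- m[, 3] * 1.1          # slightly prolate along the PF axis
    m
  })
  xyz <- sweep(xyz, 2, colMeans(xyz))
  elem <- rep(c("C", "N", "O", "C", "S"), length.out = n_atoms)
  atoms <- data.frame(serial = seq_len(n_atoms), name = "CA", element = elem,
                      resname = "GLY", resno = seq_len(n_atoms), chain = "T",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occ = 1, b = 0, stringsAsFactors = FALSE)
  structure_model(atoms, metadata = list(title = paste("pseudo-tubulin", subunit)))
}

# Place a template at lattice position: rotate by `angle_deg` about z (so the
# monomer orientation follows the PF azimuth) and translate.
place_template <- function(template, angle_deg, pos, chain) {
  R <- rotation_about_axis(c(0, 0, 1), angle_deg)
  a <- template$atoms
  xyz <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% t(R), 2, pos, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  a$chain <- chain
  a
}

#' Build an ideal singlet microtubule lattice
#'
#' Dimer k,m (PF k, axial repeat m) is placed at azimuth `k * twist_deg` and
#' axial offset `k * stagger + m * dimer_rise`, built along +z. Within each
#' dimer the beta monomer is at the lower axial position and alpha above it
#' (beta-to-alpha points to the plus end). Ground truth (PF, dimer, subunit,
#' tubule) is recorded per chain.
#'
#' @param spec lattice_spec
#' @param template optional list(alpha =, beta =) of structure_model monomers;
#'   defaults to the bundled pseudo-tubulin pair
#' @param tubule_letter chain-id prefix and truth tubule label (default "A")
#' @return structure_model with ground-truth table attached
#' @export
build_singlet <- function(spec, template = NULL, tubule_letter = "A") {
  if (is.null(template)) {
    template <- list(alpha = template_monomer("alpha", seed = spec$seed),
                     beta = template_monomer("beta", seed = spec$seed))
  }
  n_built <- if (is.null(spec$open_arc)) spec$n_pf else spec$open_arc
  if (n_built == 0) return(NULL)
  if (is.null(spec$open_arc)) {
    closure <- (spec$stagger * spec$n_pf) %% spec$monomer_rise
    closure <- min(closure, spec$monomer_rise - closure)
    if (closure > 1e-6) {
      stop(sprintf("stagger %.4f A violates lattice closure (stagger * n_pf must be a multiple of the monomer rise %.1f A); set open_arc", spec$stagger, spec$monomer_rise))
    }
  }
  rows <- list()
  truth <- list()
  for (k in seq_len(n_built) - 1) {
    ang <- k * spec$twist_deg
    base <- spec$radius * c(cos(ang * pi / 180), sin(ang * pi / 180), 0)
    # wrap the accumulated stagger into one dimer rise so every PF covers the
    # same axial window (a lattice segment cut perpendicular to the axis)
    off <- (k * spec$stagger) %% spec$dimer_rise
    for (m in seq_len(spec$n_repeats) - 1) {
      z0 <- off + m * spec$dimer_rise
      for (su in c("beta", "alpha")) {
        dz <- if (su == "beta") 0 else spec$monomer_rise
        chain <- sprintf("%s%02d%d%s", tubule_letter, k + 1, m + 1,
                         substr(su, 1, 1))
        rows[[chain]] <- place_template(template[[su]], ang,
                                        base + c(0, 0, z0 + dz), chain)
        truth[[chain]] <- data.frame(chain = chain, tubule = tubule_letter,
                                     pf = k + 1L, dimer = m + 1L,
                                     subunit = su, stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure_model(atoms,
                  metadata = list(title = "synthetic singlet lattice",
                                  spec = spec),
                  truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Build a synthetic doublet (complete A-tubule + open B-arc)
#'
#' The open B-arc is grafted outside the A-tubule between two designated A
#' PFs: the B-tubule centre sits at the azimuth bisecting the attachment pair,
#' with the B1 protofilament facing the A-tubule exterior at radial gap
#' `junction$gap` from the A wall. The arc winds in the same rotational sense
#' as the A numbering, so B10 ends up on the inner-junction side. Ground truth
#' for both tubules is recorded.
#'
#' @param spec_A closed lattice_spec for the A-tubule
#' @param spec_B lattice_spec with `open_arc` set for the B-arc (an `open_arc`
#'   of 0 returns the singlet unchanged)
#' @param junction list(attach = c(10, 11) A-PF indices, gap = 50 radial gap
#'   in A between the A wall and the B1 centroid, z_offset = 0)
#' @param template optional list(alpha =, beta =) monomer templates
#' @return structure_model with ground truth; metadata records the junction
#' @export
build_doublet <- function(spec_A = lattice_spec(13),
                          spec_B = lattice_spec(13, open_arc = 10),
                          junction = list(attach = c(10, 11), gap = 50,
                                          z_offset = 0),
                          template = NULL) {
  if (is.null(junction$gap)) junction$gap <- 50
  if (is.null(junction$z_offset)) junction$z_offset <- 0
  if (is.null(junction$attach)) junction$attach <- c(10, 11)
  if (!is.null(spec_A$open_arc) && spec_A$open_arc < spec_A$n_pf) {
    stop("spec_A must describe a closed tubule")
  }
  A <- build_singlet(spec_A, template, tubule_letter = "A")
  B <- build_singlet(spec_B, template, tubule_letter = "B")
  if (is.null(B)) return(A)
  att <- junction$attach
  phi <- spec_A$twist_deg * (att[1] - 1 + att[2] - 1) / 2   # degrees
  d <- spec_A$radius + junction$gap + spec_B$radius
  centre <- d * c(cos(phi * pi / 180), sin(phi * pi / 180), 0)
  # B1 faces the A axis: local azimuth 0 maps to phi + 180
  tr <- rigid_transform(rotation_about_axis(c(0, 0, 1), phi + 180),
                        centre + c(0, 0, junction$z_offset))
  B <- apply_transform(tr, B)
  mind <- min_cross_distance(coords(A), coords(B))
  if (mind < 2) {
    stop(sprintf("A and B atoms overlap at the graft (min distance %.2f A); increase junction$gap", mind))
  }
  out <- merge_models(A, B)
  out$metadata <- list(title = "synthetic doublet lattice", spec_A = spec_A,
                       spec_B = spec_B, junction = junction)
  out
}

#' Measure twist, rise and stagger of a built lattice
#'
#' Round-trip check for the generator: inter-PF twist and stagger come from
#' [pf_pair_geometry()] on the first non-wrap adjacent pair, and the dimer
#' rise from superposing axially consecutive dimers within one PF.
#'
#' @param model structure_model from [build_singlet()]
#' @param assignment optional pf_assignment
#' @return list(twist_deg, rise, stagger)
#' @export
measure_lattice <- function(model, assignment = NULL) {
  if (is.null(assignment)) assignment <- assign_pfs(model, max_tubules = 1)
  ap <- adjacent_pairs(assignment, "A")
  g <- pf_pair_geometry(model, assignment, ap[1, 1], ap[1, 2])
  df <- assignment$chains
  pf1 <- ap[1, 1]
  i <- which(df$pf == pf1)
  dimers <- sort(unique(df$dimer[i]))
  rise <- NA_real_
  if (length(dimers) >= 2) {
    ch1 <- df$chain[i][df$dimer[i] == dimers[1]]
    ch2 <- df$chain[i][df$dimer[i] == dimers[2]]
    m1 <- select_atoms(model, chain = ch1[order(df$z[i][df$dimer[i] == dimers[1]])])
    m2 <- select_atoms(model, chain = ch2[order(df$z[i][df$dimer[i] == dimers[2]])])
    fit <- superpose(m1, m2, pairing = dimer_pairing(
      m1, m2, unique(m1$atoms$chain), unique(m2$atoms$chain)))
    rise <- twist_about_axis(fit$transform, assignment$axis)$z_shift
  }
  list(twist_deg = g$angle_deg, rise = rise, stagger = g$z_shift)
}
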