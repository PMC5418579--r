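#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic sphere sampling: a fixed golden-section spiral point set is
#' scaled to each atom's vdW radius plus the probe radius, and the exposed
#' fraction times the sphere area gives the per-atom SASA. Hydrogens are
#' excluded by default (deposited tubulin models are heavy-atom).
#'
#' @param model structure_model
#' @param probe_radius probe radius, A (default 1.4, a water molecule)
#' @param n_sphere_points points per atom (default 960; minimum 24)
#' @param include_hydrogens logical (default FALSE)
#' @return list(atom_sasa = per-atom A^2 (0 for excluded hydrogens),
#'   total = A^2, probe_radius, n_sphere_points)
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_sphere_points = 960,
                         include_hydrogens = FALSE) {
  if (n_sphere_points < 24) stop("n_sphere_points must be >= 24")
  a <- model$atoms
  keep <- if (include_hydrogens) rep(TRUE, nrow(a)) else a$element != "H"
  per <- numeric(nrow(a))
  if (any(keep)) {
    per[keep] <- cpp_sasa(as.matrix(a[keep, c("x", "y", "z")]),
                          a$vdw[keep], probe_radius, as.integer(n_sphere_points))
  }
  list(atom_sasa = per, total = sum(per), probe_radius = probe_radius,
       n_sphere_points = n_sphere_points)
}

#' Buried surface area of a chain-chain interface
#'
#' BSA = SASA(A alone) + SASA(B alone) - SASA(A and B together), the full-sum
#' convention; the halved value (per-side average, PISA convention) is
#' returned alongside. Negative values within numerical tolerance are clipped
#' to zero.
#'
#' @param model structure_model containing both chain sets
#' @param chains_A,chains_B disjoint chain-id vectors
#' @param probe_radius,n_sphere_points as in [compute_sasa()]
#' @return list(bsa = full sum A^2, bsa_halved, sasa_A, sasa_B, sasa_AB)
#' @export
buried_surface_area <- function(model, chains_A, chains_B, probe_radius = 1.4,
                                n_sphere_points = 960) {
  if (length(chains_A) == 0 || length(chains_B) == 0) {
    stop("empty chain set")
  }
  if (length(intersect(chains_A, chains_B)) > 0) {
    stop("chain sets must be disjoint")
  }
  mA <- select_atoms(model, chain = chains_A)
  mB <- select_atoms(model, chain = chains_B)
  if (n_atoms(mA) == 0 || n_atoms(mB) == 0) stop("chain set selects no atoms")
  sA <- compute_sasa(mA, probe_radius, n_sphere_points)$total
  sB <- compute_sasa(mB, probe_radius, n_sphere_points)$total
  sAB <- compute_sasa(merge_models(mA, mB), probe_radius, n_sphere_points)$total
  bsa <- sA + sB - sAB
  if (bsa < 0) {
    if (bsa < -1) warning(sprintf("negative BSA (%.2f A^2) clipped to 0", bsa))
    bsa <- 0
  }
  list(bsa = bsa, bsa_halved = bsa / 2, sasa_A = sA, sasa_B = sB, sasa_AB = sAB)
}

salt_bridge_donors <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                           HIS = c("ND1", "NE2"))
salt_bridge_acceptors <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# Atom table of charged-group atoms on one side; role "donor"/"acceptor".
charged_atoms <- function(model, chains, role) {
  a <- model$atoms[model$atoms$chain %in% chains, ]
  tab <- if (role == "donor") salt_bridge_donors else salt_bridge_acceptors
  keep <- mapply(function(rn, nm) {
    !is.null(tab[[rn]]) && nm %in% tab[[rn]]
  }, a$resname, a$name)
  if (role == "acceptor") keep <- keep | a$name == "OXT"
  a[keep, , drop = FALSE]
}

#' Detect salt bridges across a chain partition
#'
#' A salt bridge is a donor heavy atom (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2 --
#' histidine assumed protonated) within `cutoff` of an acceptor heavy atom
#' (Asp OD1/OD2, Glu OE1/OE2, C-terminal OXT) on the other side of the
#' partition. Pairs are deduplicated to one record per residue pair, keeping
#' the minimum distance. Both donor->acceptor directions across the partition
#' are searched.
#'
#' @param model structure_model
#' @param chains_A,chains_B chain-id vectors forming the partition
#' @param cutoff heavy-atom distance cutoff, A (default 4.0)
#' @return data.frame: donor_chain, donor_resno, donor_resname, donor_atom,
#'   acceptor_chain, acceptor_resno, acceptor_resname, acceptor_atom, distance
#' @export
detect_salt_bridges <- function(model, chains_A, chains_B, cutoff = 4.0) {
  one_way <- function(don_ch, acc_ch) {
    don <- charged_atoms(model, don_ch, "donor")
    acc <- charged_atoms(model, acc_ch, "acceptor")
    if (nrow(don) == 0 || nrow(acc) == 0) return(NULL)
    pr <- cpp_cross_pairs(as.matrix(don[, c("x", "y", "z")]),
                          as.matrix(acc[, c("x", "y", "z")]), cutoff)
    if (nrow(pr) == 0) return(NULL)
    data.frame(donor_chain = don$chain[pr$i], donor_resno = don$resno[pr$i],
               donor_resname = don$resname[pr$i], donor_atom = don$name[pr$i],
               acceptor_chain = acc$chain[pr$j], acceptor_resno = acc$resno[pr$j],
               acceptor_resname = acc$resname[pr$j], acceptor_atom = acc$name[pr$j],
               distance = pr$d, stringsAsFactors = FALSE)
  }
  out <- rbind(one_way(chains_A, chains_B), one_way(chains_B, chains_A))
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_resname = character(0), donor_atom = character(0),
                      acceptor_chain = character(0), acceptor_resno = integer(0),
                      acceptor_resname = character(0), acceptor_atom = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  }
  key <- paste(out$donor_chain, out$donor_resno, out$acceptor_chain,
               out$acceptor_resno)
  out <- out[order(key, out$distance), ]
  out <- out[!duplicated(paste(out$donor_chain, out$donor_resno,
                               out$acceptor_chain, out$acceptor_resno)), ]
  out <- out[order(out$distance), ]
  rownames(out) <- NULL
  out
}

#' Count steric clashes across a chain partition
#'
#' A clash is a cross-partition heavy-atom pair whose vdW overlap
#' `r_i + r_j - distance` exceeds `overlap_threshold`.
#'
#' @param model structure_model
#' @param chains_A,chains_B chain-id vectors
#' @param overlap_threshold A (default 0.4, a severe-clash criterion)
#' @return list(n = count, records = data.frame(i_serial, j_serial, distance,
#'   overlap) in deterministic order)
#' @export
count_clashes <- function(model, chains_A, chains_B, overlap_threshold = 0.4) {
  a <- model$atoms[model$atoms$chain %in% chains_A & model$atoms$element != "H", ]
  b <- model$atoms[model$atoms$chain %in% chains_B & model$atoms$element != "H", ]
  empty <- data.frame(i_serial = integer(0), j_serial = integer(0),
                      distance = numeric(0), overlap = numeric(0))
  if (nrow(a) == 0 || nrow(b) == 0) return(list(n = 0L, records = empty))
  cutoff <- max(a$vdw) + max(b$vdw) - overlap_threshold
  pr <- cpp_cross_pairs(as.matrix(a[, c("x", "y", "z")]),
                        as.matrix(b[, c("x", "y", "z")]), cutoff)
  if (nrow(pr) == 0) return(list(n = 0L, records = empty))
  ov <- a$vdw[pr$i] + b$vdw[pr$j] - pr$d
  keep <- ov > overlap_threshold
  rec <- data.frame(i_serial = a$serial[pr$i][keep],
                    j_serial = b$serial[pr$j][keep],
                    distance = pr$d[keep], overlap = ov[keep])
  rec <- rec[order(rec$i_serial, rec$j_serial), ]
  rownames(rec) <- NULL
  list(n = nrow(rec), records = rec)
}

# Coarse Lennard-Jones parameters by element (epsilon in score units,
# sigma in A); combined with Lorentz-Berthelot rules.
lj_params <- function(element) {
  eps <- c(C = 0.10, N = 0.17, O = 0.21, S = 0.25, P = 0.20, H = 0.016)
  sig <- c(C = 3.40, N = 3.25, O = 2.96, S = 3.50, P = 3.70, H = 2.50)
  el <- toupper(element)
  e <- eps[el]; s <- sig[el]
  miss <- is.na(e)
  list(eps = unname(ifelse(miss, NA, e)), sig = unname(ifelse(miss, NA, s)),
       missing = miss)
}

# Formal-charge sites: one pseudo-particle per charged residue at the
# side-chain charged-group centroid. Histidine is treated as protonated (+1).
charge_sites <- function(model, chains) {
  groups <- list(ARG = list(atoms = c("NH1", "NH2", "NE", "CZ"), q = +1),
                 LYS = list(atoms = "NZ", q = +1),
                 HIS = list(atoms = c("ND1", "NE2", "CE1"), q = +1),
                 ASP = list(atoms = c("OD1", "OD2", "CG"), q = -1),
                 GLU = list(atoms = c("OE1", "OE2", "CD"), q = -1))
  a <- model$atoms[model$atoms$chain %in% chains, ]
  a <- a[a$resname %in% names(groups), ]
  if (nrow(a) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      q = numeric(0)))
  }
  out <- lapply(split(a, paste(a$chain, a$resno)), function(res) {
    g <- groups[[res$resname[1]]]
    sel <- res[res$name %in% g$atoms, ]
    if (nrow(sel) == 0) return(NULL)
    data.frame(x = mean(sel$x), y = mean(sel$y), z = mean(sel$z), q = g$q)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out)) data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                               q = numeric(0)) else out
}

#' Cutoff nonbonded interface score
#'
#' A simplified pairwise score used as a comparator (stronger/weaker), not an
#' energy in kcal/mol. Electrostatics: formal +/-1 charges on Arg/Lys/His+ and
#' Asp-/Glu- side-chain centroids, Coulomb term damped by the shift function
#' `(1 - (r/r_c)^2)^2` which vanishes exactly at the cutoff. Van der Waals:
#' element-wise Lennard-Jones damped by a cubic switching function equal to 1
#' below `switch_on` and 0 above `cutoff`. Atoms with missing parameters are
#' skipped and reported.
#'
#' @param model structure_model
#' @param chains_A,chains_B chain-id vectors
#' @param cutoff nonbonded cutoff, A (default 8.5)
#' @param switch_on start of the vdW switching region, A (default 6.5)
#' @return list(eelec, evdw, skipped_elements)
#' @export
nonbonded_score <- function(model, chains_A, chains_B, cutoff = 8.5,
                            switch_on = 6.5) {
  kc <- 332.0636                       # Coulomb constant, score units
  qa <- charge_sites(model, chains_A)
  qb <- charge_sites(model, chains_B)
  eelec <- 0
  if (nrow(qa) > 0 && nrow(qb) > 0) {
    pr <- cpp_cross_pairs(as.matrix(qa[, 1:3]), as.matrix(qb[, 1:3]), cutoff)
    if (nrow(pr) > 0) {
      r <- pr$d
      shift <- (1 - (r / cutoff)^2)^2
      eelec <- sum(kc * qa$q[pr$i] * qb$q[pr$j] / r * shift)
    }
  }
  a <- model$atoms[model$atoms$chain %in% chains_A & model$atoms$element != "H", ]
  b <- model$atoms[model$atoms$chain %in% chains_B & model$atoms$element != "H", ]
  pa <- lj_params(a$element); pb <- lj_params(b$element)
  skipped <- unique(c(a$element[pa$missing], b$element[pb$missing]))
  a <- a[!pa$missing, ]; b <- b[!pb$missing, ]
  evdw <- 0
  if (nrow(a) > 0 && nrow(b) > 0) {
    pa <- lj_params(a$element); pb <- lj_params(b$element)
    pr <- cpp_cross_pairs(as.matrix(a[, c("x", "y", "z")]),
                          as.matrix(b[, c("x", "y", "z")]), cutoff)
    if (nrow(pr) > 0) {
      r <- pr$d
      eps <- sqrt(pa$eps[pr$i] * pb$eps[pr$j])
      sig <- (pa$sig[pr$i] + pb$sig[pr$j]) / 2
      sr6 <- (sig / r)^6
      lj <- 4 * eps * (sr6^2 - sr6)
      sw <- vdw_switch(r, switch_on, cutoff)
      evdw <- sum(lj * sw)
    }
  }
  list(eelec = eelec, evdw = evdw, skipped_elements = skipped)
}

# CHARMM-style cubic switching function: 1 below r_on, 0 above r_off.
vdw_switch <- function(r, r_on, r_off) {
  s <- rep(1, length(r))
  mid <- r > r_on & r <= r_off
  ro2 <- r_off^2; rn2 <- r_on^2
  r2 <- r[mid]^2
  s[mid] <- (ro2 - r2)^2 * (ro2 + 2 * r2 - 3 * rn2) / (ro2 - rn2)^3
  s[r > r_off] <- 0
  s
}

#' Full interface report for one chain partition
#'
#' Aggregates buried surface area, salt bridges, steric clashes and the
#' nonbonded score for one chain-pair interface.
#'
#' @param model structure_model
#' @param chains_A,chains_B chain-id vectors
#' @param probe_radius,n_sphere_points SASA controls
#' @param salt_bridge_cutoff,clash_overlap,nb_cutoff,nb_switch_on thresholds
#' @return one-row data.frame: chains_A, chains_B, bsa, bsa_halved,
#'   n_salt_bridges, bridges (list column), n_clashes, eelec, evdw
#' @export
interface_report <- function(model, chains_A, chains_B, probe_radius = 1.4,
                             n_sphere_points = 960, salt_bridge_cutoff = 4.0,
                             clash_overlap = 0.4, nb_cutoff = 8.5,
                             nb_switch_on = 6.5) {
  bsa <- buried_surface_area(model, chains_A, chains_B, probe_radius,
                             n_sphere_points)
  sb <- detect_salt_bridges(model, chains_A, chains_B, salt_bridge_cutoff)
  cl <- count_clashes(model, chains_A, chains_B, clash_overlap)
  nb <- nonbonded_score(model, chains_A, chains_B, nb_cutoff, nb_switch_on)
  out <- data.frame(chains_A = paste(chains_A, collapse = "+"),
                    chains_B = paste(chains_B, collapse = "+"),
                    bsa = bsa$bsa, bsa_halved = bsa$bsa_halved,
                    n_salt_bridges = nrow(sb), n_clashes = cl$n,
                    eelec = nb$eelec, evdw = nb$evdw,
                    stringsAsFactors = FALSE)
  out$bridges <- list(sb)
  out
}

#' The six outer-junction interfaces
#'
#' Convenience wrapper producing the interface table for the outer junction of
#' a doublet: A10a-A11a, A10b-A11b, A10a-B1a, A10b-B1b, A11a-B1a and A11b-B1b
#' (a = alpha, b = beta), given a PF assignment and alpha/beta chain labels.
#' Uses the representative dimer of each PF.
#'
#' @param model structure_model
#' @param assignment pf_assignment with labels A10, A11, B1
#' @param subunits optional chain -> "alpha"/"beta" labels
#' @param ... passed to [interface_report()]
#' @return data.frame, one row per interface
#' @export
outer_junction_interfaces <- function(model, assignment, subunits = NULL, ...) {
  sub <- subunit_labels(model, subunits, required = TRUE)
  pick <- function(pf, su) {
    ch <- rep_dimer_chains(assignment, pf)
    ch[sub[ch] == su]
  }
  pairs <- list(c("A10", "A11", "alpha"), c("A10", "A11", "beta"),
                c("A10", "B1", "alpha"), c("A10", "B1", "beta"),
                c("A11", "B1", "alpha"), c("A11", "B1", "beta"))
  rows <- lapply(pairs, function(p) {
    r <- interface_report(model, pick(p[1], p[3]), pick(p[2], p[3]), ...)
    r$interface <- sprintf("%s%s-%s%s", p[1], substr(p[3], 1, 1),
                           p[2], substr(p[3], 1, 1))
    r
  })
  out <- do.call(rbind, rows)
  out[, c("interface", setdiff(names(out), "interface"))]
}

#' Minimum heavy-atom distance between two coordinate sets
#' @param A,B n x 3 coordinate matrices
#' @return distance in A
#' @export
min_cross_distance <- function(A, B) cpp_min_dist(as.matrix(A), as.matrix(B))
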