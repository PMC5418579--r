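#' Lattice (longitudinal) axis
#'
#' @param direction unit 3-vector; the + sense points toward the microtubule
#'   plus end
#' @param point a point on the axis, Angstrom
#' @return object of class `lattice_axis`
#' @export
lattice_axis <- function(direction, point = c(0, 0, 0)) {
  n <- sqrt(sum(direction^2))
  if (n < 1e-12) stop("zero-length axis direction")
  structure(list(direction = unname(direction) / n,
                 point = unname(as.numeric(point))),
            class = "lattice_axis")
}

#' @export
print.lattice_axis <- function(x, ...) {
  cat(sprintf("lattice_axis: direction (%.4f, %.4f, %.4f) through (%.2f, %.2f, %.2f)\n",
              x$direction[1], x$direction[2], x$direction[3],
              x$point[1], x$point[2], x$point[3]))
  invisible(x)
}

#' Estimate the microtubule longitudinal axis
#'
#' The direction comes from the axial stacking of tubulin monomers: in a
#' microtubule lattice the nearest neighbour of each chain centroid is its
#' axial (intradimer) partner 40 A away, closer than the ~53 A lateral PF
#' spacing, so the sign-aligned mean of nearest-neighbour displacement vectors
#' points along the longitudinal axis (exactly so for ideal lattices). The
#' axis point is the centroid. Displacements must be mutually consistent
#' (mean |cos| to the axis > 0.9); irregular clouds are rejected. The sign is
#' fixed so that the beta-to-alpha vector within each dimer has a positive
#' projection (plus end up) when subunit identities are available (from
#' `subunits` or the model's generator ground truth); otherwise the component
#' of largest magnitude is made positive.
#'
#' @param model structure_model spanning at least 3 protofilaments or 2 axial
#'   repeats (a single dimer is an error)
#' @param subunits optional named character vector chain -> "alpha"/"beta"
#' @return lattice_axis
#' @export
estimate_axis <- function(model, subunits = NULL) {
  cc <- chain_centroids(model)
  if (nrow(cc) < 3) {
    stop("too few chains to estimate an axis; supply at least 3 ",
         "protofilaments or 2 axial repeats")
  }
  ctr <- colMeans(cc)
  D <- t(vapply(seq_len(nrow(cc)), function(i) {
    d2 <- rowSums(sweep(cc, 2, cc[i, ])^2)
    d2[i] <- Inf
    cc[which.min(d2), ] - cc[i, ]
  }, numeric(3)))
  len <- sqrt(rowSums(D^2))
  keep <- len <= 1.5 * stats::median(len) & len > 1e-9
  V <- D[keep, , drop = FALSE] / len[keep]
  n <- V[1, ]
  for (iter in 1:5) {
    s <- sign(as.numeric(V %*% n))
    s[s == 0] <- 1
    n <- colMeans(V * s)
    nn <- sqrt(sum(n^2))
    if (nn < 1e-12) break
    n <- n / nn
  }
  # drop displacements that are not axial (e.g. lateral neighbours of very
  # low-curvature PF pairs, which can be closer than the intradimer partner)
  for (iter in 1:3) {
    keep2 <- abs(as.numeric(V %*% n)) > 0.8
    if (sum(keep2) < 3) break
    s <- sign(as.numeric(V[keep2, , drop = FALSE] %*% n))
    s[s == 0] <- 1
    m <- colMeans(V[keep2, , drop = FALSE] * s)
    if (sqrt(sum(m^2)) < 1e-12) break
    n <- m / sqrt(sum(m^2))
  }
  kept <- abs(as.numeric(V %*% n)) > 0.8
  consistency <- mean(abs(as.numeric(V[kept, , drop = FALSE] %*% n)))
  if (!is.finite(consistency) || mean(kept) < 0.5 || consistency < 0.9) {
    stop("chain packing has no consistent stacking direction ",
         "(near-isotropic point cloud); supply a longer lattice segment")
  }
  sub <- subunit_labels(model, subunits, required = FALSE)
  if (!is.null(sub) && !is.null(model$truth) &&
      all(c("pf", "dimer") %in% names(model$truth))) {
    tr <- model$truth
    proj <- 0
    for (key in unique(paste(tr$tubule, tr$pf, tr$dimer))) {
      ch <- tr$chain[paste(tr$tubule, tr$pf, tr$dimer) == key]
      al <- ch[sub[ch] == "alpha"]; be <- ch[sub[ch] == "beta"]
      if (length(al) == 1 && length(be) == 1) {
        proj <- proj + sum((cc[al, ] - cc[be, ]) * n)
      }
    }
    if (proj < 0) n <- -n
  } else if (n[which.max(abs(n))] < 0) {
    n <- -n
  }
  lattice_axis(n, ctr)
}

#' Twist-swing decomposition of a rigid transform about a lattice axis
#'
#' Splits the rotation into a twist about `axis` and a residual swing, and
#' reports the axial component of the screw translation. `axis_deviation_deg`
#' is the (unsigned, folded to 0-90) angle between the transform's own
#' rotation axis and the lattice axis; rotations smaller than 1e-6 degrees are
#' flagged `degenerate` and reported as twist 0, deviation 0.
#'
#' @param t rigid_transform
#' @param axis lattice_axis
#' @return list(twist_deg, z_shift, axis_deviation_deg, degenerate)
#' @export
twist_about_axis <- function(t, axis) {
  n <- axis$direction
  q <- rotation_to_quaternion(t$rotation)
  proj <- sum(q[2:4] * n)
  twist <- 2 * atan2(proj, q[1]) * 180 / pi
  twist <- ((twist + 180) %% 360) - 180
  p <- axis$point
  z_shift <- sum(n * (as.numeric(t$rotation %*% p) + t$translation - p))
  aa <- rotation_axis_angle(t$rotation)
  if (aa$angle_deg < 1e-6) {
    return(list(twist_deg = 0, z_shift = z_shift, axis_deviation_deg = 0,
                degenerate = TRUE))
  }
  cosd <- min(1, abs(sum(aa$axis * n)))
  list(twist_deg = twist, z_shift = z_shift,
       axis_deviation_deg = acos(cosd) * 180 / pi, degenerate = FALSE)
}

# Resolve per-chain alpha/beta labels: explicit argument wins, then generator
# ground truth. Returns NULL (or errors when required) if unknown.
subunit_labels <- function(model, subunits = NULL, required = TRUE) {
  if (!is.null(subunits)) {
    return(structure(as.character(subunits), names = names(subunits)))
  }
  tr <- model$truth
  if (!is.null(tr) && "subunit" %in% names(tr)) {
    return(structure(as.character(tr$subunit), names = tr$chain))
  }
  if (required) {
    stop("alpha/beta chain identities unknown; pass `subunits` or use ",
         "assign_alpha_beta_register() on a density map")
  }
  NULL
}
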