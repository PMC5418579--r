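#' Simulate a density map from an atomic model
#'
#' Each atom is rendered as an isotropic 3-D Gaussian of width
#' `sigma = resolution / (pi * sqrt(2))` whose integral is proportional to the
#' atomic number; values are scaled so the plain sum over voxels equals the
#' total weight (up to truncation at 4 sigma and grid edges). The grid covers
#' the model bounding box plus `pad` on every side.
#'
#' @param model structure_model
#' @param resolution target resolution, A (must be >= 2 * voxel_size)
#' @param voxel_size A per voxel
#' @param pad margin around the model, A (default 3 * sigma)
#' @param grid optional existing density_grid whose geometry (dims, voxel,
#'   origin) should be reused; values are ignored
#' @return density_grid
#' @export
simulate_density <- function(model, resolution, voxel_size, pad = NULL,
                             grid = NULL) {
  if (resolution < 2 * voxel_size) {
    stop(sprintf("resolution %.2f A undersampled at voxel %.2f A (need >= 2 voxels)",
                 resolution, voxel_size))
  }
  sigma <- resolution / (pi * sqrt(2))
  if (is.null(pad)) pad <- 3 * sigma
  xyz <- coords(model)
  if (is.null(grid)) {
    lo <- apply(xyz, 2, min) - pad - 4 * sigma
    hi <- apply(xyz, 2, max) + pad + 4 * sigma
    dims <- as.integer(ceiling((hi - lo) / voxel_size)) + 1L
    origin <- lo
  } else {
    dims <- grid_dims(grid)
    origin <- grid$origin
    voxel_size <- grid$voxel
  }
  w <- atomic_number(model$atoms$element)
  vals <- cpp_gaussian_splat(xyz, w, sigma, origin, voxel_size, dims, 4.0)
  density_grid(array(vals, dim = rev(dims)), voxel_size, origin)
}

#' Real-space cross-correlation of two grids
#'
#' Pearson correlation over the full grid or a logical mask. Grids must share
#' shape and voxel size; resample first otherwise.
#'
#' @param grid_a,grid_b density_grid
#' @param mask optional logical array of the same shape
#' @return correlation in [-1, 1]
#' @export
real_space_cc <- function(grid_a, grid_b, mask = NULL) {
  if (!all(dim(grid_a$values) == dim(grid_b$values))) {
    stop("grids differ in shape; resample first")
  }
  a <- grid_a$values
  b <- grid_b$values
  if (!is.null(mask)) {
    a <- a[mask]
    b <- b[mask]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(as.vector(a), as.vector(b))
}

# Resample `grid` onto the geometry of `target`, optionally pretending that
# `grid`'s voxel size (and origin scale) is `voxel_as`. Trilinear; outside = 0.
resample_grid <- function(grid, target, voxel_as = NULL) {
  voxel <- if (is.null(voxel_as)) grid$voxel else voxel_as
  scale <- voxel / grid$voxel
  origin <- grid$origin * scale
  d <- grid_dims(target)
  ix <- seq_len(d[1]) - 1
  iy <- seq_len(d[2]) - 1
  iz <- seq_len(d[3]) - 1
  pts <- cbind(
    x = rep(target$origin[1] + target$voxel * ix, times = d[2] * d[3]),
    y = rep(rep(target$origin[2] + target$voxel * iy, each = d[1]), times = d[3]),
    z = rep(target$origin[3] + target$voxel * iz, each = d[1] * d[2]))
  frac <- sweep(pts, 2, origin) / voxel
  v <- cpp_trilinear(grid$values, grid_dims(grid), frac, 0)
  arr <- aperm(array(v, dim = d), c(3, 2, 1))
  density_grid(arr, target$voxel, target$origin)
}

#' Calibrate the voxel size of an experimental map against a fitted model
#'
#' Scans voxel-size scale factors: at each scale the experimental grid is
#' reinterpreted with the scaled voxel (world coordinates, including the
#' origin, scale accordingly) and the model is simulated directly onto that
#' geometry -- no interpolation -- and correlated with the experimental
#' values; a parabolic sub-step refinement around the best scan point gives
#' the returned voxel size. Mirrors the magnification calibration used to
#' correct nominal cryo-EM pixel sizes.
#'
#' @param exp_map density_grid with a nominal (possibly mislabelled) voxel
#' @param model structure_model roughly pre-fitted to the map
#' @param resolution resolution at which the model is simulated, A
#' @param nominal_voxel nominal voxel size, A (default exp_map$voxel)
#' @param scan relative scan half-width (default 0.03) and step (0.001)
#' @param scan_step relative scan step (default 0.001)
#' @return list(voxel_size, scale, cc, scan = data.frame(scale, cc))
#' @export
calibrate_voxel_size <- function(exp_map, model, resolution,
                                 nominal_voxel = NULL, scan = 0.03,
                                 scan_step = 0.001) {
  if (is.null(nominal_voxel)) nominal_voxel <- exp_map$voxel
  if (stats::sd(exp_map$values) == 0) stop("flat experimental map: zero variance")
  scales <- seq(1 - scan, 1 + scan, by = scan_step)
  ccs <- vapply(scales, function(s) {
    geom <- density_grid(exp_map$values, nominal_voxel * s, exp_map$origin * s)
    sim <- simulate_density(model, resolution, grid = geom,
                            voxel_size = nominal_voxel * s)
    suppressWarnings(tryCatch(real_space_cc(geom, sim), error = function(e) NA))
  }, numeric(1))
  ok <- which(!is.na(ccs))
  best <- ok[which.max(ccs[ok])]
  if (best == 1 || best == length(scales)) {
    warning("correlation maximum at the scan edge; widen the scan")
    s_hat <- scales[best]
  } else {
    # parabolic refinement through the three points around the maximum
    y1 <- ccs[best - 1]; y2 <- ccs[best]; y3 <- ccs[best + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) < 1e-15) 0 else 0.5 * (y1 - y3) / denom
    s_hat <- scales[best] + delta * scan_step
  }
  list(voxel_size = s_hat * nominal_voxel, scale = s_hat, cc = ccs[best],
       scan = data.frame(scale = scales, cc = ccs))
}

#' Difference map (experimental minus scaled simulated density)
#'
#' The simulated map is least-squares scaled (gain + offset) to the
#' experimental map over the model-footprint mask only -- so densities absent
#' from the model (e.g. microtubule inner proteins) do not bias the fit -- and
#' subtracted.
#'
#' @param exp_map,sim_map density_grid of identical geometry
#' @param mask optional logical array over which to fit the scaling; defaults
#'   to the simulated-map footprint (sim > 5% of its maximum)
#' @return density_grid of exp - (gain * sim + offset)
#' @export
difference_map <- function(exp_map, sim_map, mask = NULL) {
  if (!all(dim(exp_map$values) == dim(sim_map$values))) {
    stop("grids differ in shape; resample first")
  }
  if (is.null(mask)) mask <- sim_map$values > 0.05 * max(sim_map$values)
  s <- sim_map$values[mask]
  e <- exp_map$values[mask]
  if (stats::var(s) == 0) stop("degenerate scaling: simulated map has zero variance over the mask")
  gain <- stats::cov(e, s) / stats::var(s)
  offset <- mean(e) - gain * mean(s)
  density_grid(exp_map$values - (gain * sim_map$values + offset),
               exp_map$voxel, exp_map$origin)
}

#' Assign alpha/beta register per protofilament by 4-nm-shift correlation
#'
#' For each PF, the density simulated from its fitted dimer is correlated with
#' the experimental map at the fitted position (register 0) and shifted by
#' `shift` (default 40 A, one monomer) along the lattice axis; the register
#' with the larger correlation wins. The correlation mask is the union of the
#' two simulated footprints. Ties (confidence below `tie_tol`) are flagged
#' ambiguous.
#'
#' @param exp_map density_grid covering the dimers
#' @param model structure_model whose chains are the fitted monomers
#' @param assignment pf_assignment
#' @param resolution simulation resolution, A
#' @param shift axial shift, A (default 40)
#' @param tie_tol ambiguity threshold on |cc0 - cc4| (default 1e-3)
#' @return data.frame: pf, cc0, cc4, register ("register-0"/"register-+4nm"),
#'   confidence, ambiguous
#' @export
assign_alpha_beta_register <- function(exp_map, model, assignment, resolution,
                                       shift = 40, tie_tol = 1e-3) {
  axis <- assignment$axis
  pfs <- unique(assignment$chains$pf)
  pfs <- pfs[order(match(substr(pfs, 1, 1), c("A", "B")),
                   as.integer(sub("^[AB]", "", pfs)))]
  rows <- lapply(pfs, function(pf) {
    ch <- rep_dimer_chains(assignment, pf)
    dimer <- select_atoms(model, chain = ch)
    sim0 <- simulate_density(dimer, resolution, exp_map$voxel, grid = exp_map)
    shifted <- dimer
    coords(shifted) <- sweep(coords(dimer), 2, shift * axis$direction, "+")
    sim4 <- simulate_density(shifted, resolution, exp_map$voxel, grid = exp_map)
    mask <- sim0$values > 0.05 * max(sim0$values) |
            sim4$values > 0.05 * max(sim4$values)
    if (!any(mask)) stop("dimer mask falls outside the map for PF ", pf)
    cc0 <- real_space_cc(exp_map, sim0, mask)
    cc4 <- real_space_cc(exp_map, sim4, mask)
    data.frame(pf = pf, cc0 = cc0, cc4 = cc4,
               register = if (cc0 >= cc4) "register-0" else "register-+4nm",
               confidence = abs(cc0 - cc4),
               ambiguous = abs(cc0 - cc4) < tie_tol,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract oriented subvolumes around dimer centres
#'
#' Each subvolume is resampled by trilinear interpolation into a common cubic
#' frame: subvolume voxel coordinates are mapped through the dimer's rigid
#' transform (common frame -> map frame) and sampled from the map. Boxes
#' extending outside the map are skipped with a warning.
#'
#' @param exp_map density_grid
#' @param centers n x 3 matrix of dimer centres (map world coordinates, A)
#' @param transforms list of rigid_transform mapping the common frame
#'   (centred on the origin) into the map frame at each dimer; identity
#'   transforms give axis-aligned crops
#' @param box_size box edge, voxels (odd recommended)
#' @param labels optional character vector naming each subvolume
#' @return object of class `subvolume_set`: list(volumes = list of
#'   density_grid, transforms, labels, box_size, voxel)
#' @export
extract_subvolumes <- function(exp_map, centers, transforms = NULL,
                               box_size = 32, labels = NULL) {
  centers <- matrix(centers, ncol = 3)
  n <- nrow(centers)
  if (is.null(transforms)) {
    transforms <- replicate(n, rigid_transform(), simplify = FALSE)
  }
  if (is.null(labels)) labels <- sprintf("sv%02d", seq_len(n))
  d <- grid_dims(exp_map)
  if (box_size > min(d)) stop("box larger than the map")
  voxel <- exp_map$voxel
  half <- (box_size - 1) / 2
  offs <- (seq_len(box_size) - 1 - half) * voxel
  local <- cbind(
    x = rep(offs, times = box_size^2),
    y = rep(rep(offs, each = box_size), times = box_size),
    z = rep(offs, each = box_size^2))
  vols <- list()
  kept <- integer(0)
  for (i in seq_len(n)) {
    world <- sweep(local %*% t(transforms[[i]]$rotation), 2, centers[i, ], "+")
    frac <- sweep(world, 2, exp_map$origin) / voxel
    if (any(frac < 0) || any(frac[, 1] > d[1] - 1) || any(frac[, 2] > d[2] - 1) ||
        any(frac[, 3] > d[3] - 1)) {
      warning("subvolume ", labels[i], " extends outside the map; skipped")
      next
    }
    v <- cpp_trilinear(exp_map$values, d, frac, 0)
    arr <- aperm(array(v, dim = rep(box_size, 3)), c(3, 2, 1))
    vols[[length(vols) + 1]] <- density_grid(arr, voxel,
                                             origin = -half * voxel * c(1, 1, 1))
    kept <- c(kept, i)
  }
  structure(list(volumes = vols, transforms = transforms[kept],
                 labels = labels[kept], box_size = box_size, voxel = voxel),
            class = "subvolume_set")
}

#' @export
print.subvolume_set <- function(x, ...) {
  cat(sprintf("subvolume_set: %d boxes of %d^3 voxels (%.3f A/voxel)\n",
              length(x$volumes), x$box_size, x$voxel))
  invisible(x)
}

#' Average a set of subvolumes
#'
#' Voxel-wise mean, optionally preceded by a local rigid re-alignment of each
#' subvolume to the running average (coordinate-wise grid search over axial
#' rotations up to +/-5 degrees and translations up to +/-3 voxels, with
#' parabolic sub-step refinement).
#'
#' @param s subvolume_set with >= 2 members
#' @param refine logical; locally re-align before the final mean
#' @return density_grid of the average
#' @export
average_subvolumes <- function(s, refine = FALSE) {
  if (length(s$volumes) < 2) stop("need at least 2 subvolumes")
  avg <- Reduce(`+`, lapply(s$volumes, `[[`, "values")) / length(s$volumes)
  ref <- density_grid(avg, s$voxel, s$volumes[[1]]$origin)
  if (!refine) return(ref)
  aligned <- lapply(s$volumes, function(v) refine_subvolume(v, ref))
  density_grid(Reduce(`+`, lapply(aligned, `[[`, "values")) / length(aligned),
               s$voxel, ref$origin)
}

# Re-align one subvolume to a reference: sequential 1-D searches over
# translations (+/-3 voxels) then rotations about x/y/z (+/-5 deg). The
# refined pose is kept only when it improves the correlation -- resampling
# smooths the volume, so a null adjustment must not degrade aligned members.
refine_subvolume <- function(vol, ref) {
  params <- c(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0)
  score <- function(p) {
    moved <- transform_subvolume(vol, p)
    suppressWarnings(tryCatch(real_space_cc(moved, ref), error = function(e) -1))
  }
  cc0 <- suppressWarnings(tryCatch(real_space_cc(vol, ref),
                                   error = function(e) -1))
  for (pass in 1:2) {
    for (k in seq_along(params)) {
      grid <- if (k > 3) seq(-5, 5, by = 1) else seq(-3, 3, by = 1) * vol$voxel
      vals <- vapply(grid, function(g) {
        p <- params; p[k] <- g; score(p)
      }, numeric(1))
      b <- which.max(vals)
      best <- grid[b]
      if (b > 1 && b < length(grid)) {
        y1 <- vals[b - 1]; y2 <- vals[b]; y3 <- vals[b + 1]
        den <- y1 - 2 * y2 + y3
        if (abs(den) > 1e-15) {
          best <- grid[b] + 0.5 * (y1 - y3) / den * (grid[2] - grid[1])
        }
      }
      params[k] <- best
    }
  }
  if (score(params) <= cc0 + 1e-4) return(vol)
  transform_subvolume(vol, params)
}

transform_subvolume <- function(vol, p) {
  R <- rotation_about_axis(c(0, 0, 1), p["rz"]) %*%
       rotation_about_axis(c(0, 1, 0), p["ry"]) %*%
       rotation_about_axis(c(1, 0, 0), p["rx"])
  d <- grid_dims(vol)
  ix <- (seq_len(d[1]) - 1) * vol$voxel + vol$origin[1]
  pts <- cbind(x = rep(ix, times = d[2] * d[3]),
               y = rep(rep(ix, each = d[1]), times = d[3]),
               z = rep(ix, each = d[1] * d[2]))
  world <- sweep(pts %*% t(R), 2, c(p["tx"], p["ty"], p["tz"]), "+")
  frac <- sweep(world, 2, vol$origin) / vol$voxel
  v <- cpp_trilinear(vol$values, d, frac, 0)
  density_grid(aperm(array(v, dim = d), c(3, 2, 1)), vol$voxel, vol$origin)
}
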