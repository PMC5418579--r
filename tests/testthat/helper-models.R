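# Shared fixture builders and independent oracles, all generated in code.

# Minimal structure from a compact spec: one row per atom.
toy_model <- function(name, element, resname, chain, xyz, resno = NULL) {
  n <- length(name)
  if (is.null(resno)) resno <- seq_len(n)
  structure_model(data.frame(
    serial = seq_len(n), name = name, element = element, resname = resname,
    resno = resno, chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

single_atom <- function(element = "C", pos = c(0, 0, 0)) {
  toy_model("CA", element, "GLY", "A", matrix(pos, 1))
}

two_chain_atoms <- function(sep, element = "C") {
  toy_model(c("CA", "CA"), element, "GLY", c("A", "B"),
            rbind(c(0, 0, 0), c(sep, 0, 0)))
}

# Arg/Glu pair with a guanidinium nitrogen at `dist` from a carboxylate oxygen.
arg_glu_pair <- function(dist) {
  toy_model(name = c("NH1", "CZ", "OE1", "CD"),
            element = c("N", "C", "O", "C"),
            resname = c("ARG", "ARG", "GLU", "GLU"),
            chain = c("A", "A", "B", "B"),
            resno = c(1, 1, 2, 2),
            xyz = rbind(c(0, 0, 0), c(-1.3, 0, 0),
                        c(dist, 0, 0), c(dist + 1.3, 0, 0)))
}

# Monte-Carlo SASA oracle: uniform points on each expanded sphere, fraction
# not occluded by any other expanded sphere.
mc_sasa <- function(model, probe = 1.4, n_samples = 20000, seed = 1) {
  a <- model$atoms[model$atoms$element != "H", ]
  r <- a$vdw + probe
  tot <- 0
  set.seed(seed)
  for (i in seq_len(nrow(a))) {
    u <- matrix(stats::rnorm(n_samples * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * r[i], 2, c(a$x[i], a$y[i], a$z[i]), "+")
    free <- rep(TRUE, n_samples)
    for (j in seq_len(nrow(a))[-i]) {
      d2 <- (pts[, 1] - a$x[j])^2 + (pts[, 2] - a$y[j])^2 + (pts[, 3] - a$z[j])^2
      free <- free & d2 >= r[j]^2
    }
    tot <- tot + 4 * pi * r[i]^2 * mean(free)
  }
  tot
}

# Brute-force O(n^2) cross-partition clash count.
brute_clashes <- function(model, chains_A, chains_B, thr = 0.4) {
  a <- model$atoms[model$atoms$chain %in% chains_A & model$atoms$element != "H", ]
  b <- model$atoms[model$atoms$chain %in% chains_B & model$atoms$element != "H", ]
  n <- 0
  for (i in seq_len(nrow(a))) {
    d <- sqrt((a$x[i] - b$x)^2 + (a$y[i] - b$y)^2 + (a$z[i] - b$z)^2)
    n <- n + sum(a$vdw[i] + b$vdw - d > thr)
  }
  n
}

# Brute-force real-space Gaussian renderer: no truncation, plain R loops over
# atoms (vectorised over voxels). Independent of the compiled splatter.
brute_density <- function(model, resolution, grid) {
  sigma <- resolution / (pi * sqrt(2))
  d <- grid_dims(grid)
  ax <- grid$origin[1] + grid$voxel * (seq_len(d[1]) - 1)
  ay <- grid$origin[2] + grid$voxel * (seq_len(d[2]) - 1)
  az <- grid$origin[3] + grid$voxel * (seq_len(d[3]) - 1)
  w <- atomic_number(model$atoms$element)
  norm <- grid$voxel^3 / ((2 * pi)^1.5 * sigma^3)
  vals <- array(0, dim = dim(grid$values))
  xyz <- coords(model)
  for (i in seq_len(nrow(xyz))) {
    gx <- exp(-(ax - xyz[i, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ay - xyz[i, 2])^2 / (2 * sigma^2))
    gz <- exp(-(az - xyz[i, 3])^2 / (2 * sigma^2))
    vals <- vals + w[i] * norm * outer(gz, outer(gy, gx, "*"), "*")
  }
  density_grid(vals, grid$voxel, grid$origin)
}

# Grid-search oracle for the twist component: the angle t minimising the
# residual swing |R - R_axis(t)| over a 0.001-degree grid.
grid_search_twist <- function(R, axis_dir) {
  obj <- function(t) {
    S <- R %*% t(rotation_about_axis(axis_dir, t))   # residual swing
    rotation_axis_angle(S)$angle_deg
  }
  coarse <- seq(-180, 180, by = 1)
  t0 <- coarse[which.min(vapply(coarse, obj, numeric(1)))]
  fine <- seq(t0 - 1, t0 + 1, by = 0.001)
  fine[which.min(vapply(fine, obj, numeric(1)))]
}

# Small alignment fixture: `n_per_group` sequences per group; within the
# ciliated group the given columns are held fixed, within the other group they
# are randomised over `alphabet`.
toy_alignment <- function(ref = "MTGAGKW", vary_cols = 2:6, n_per_group = 6,
                          seed = 7) {
  refv <- strsplit(ref, "")[[1]]
  alphabet <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], refv)
  with_seed <- get("with_seed", asNamespace("doubletlattice"))
  seqs <- with_seed(seed, {
    cil <- replicate(n_per_group, paste(refv, collapse = ""))
    # every varied column carries n distinct residues across the group
    col_res <- lapply(vary_cols, function(j) sample(alphabet, n_per_group))
    non <- vapply(seq_len(n_per_group), function(i) {
      v <- refv
      v[vary_cols] <- vapply(col_res, `[`, character(1), i)
      paste(v, collapse = "")
    }, character(1))
    c(cil, non)
  })
  names(seqs) <- c(paste0("cil", seq_len(n_per_group)),
                   paste0("non", seq_len(n_per_group)))
  groups <- stats::setNames(rep(c("ciliated", "non-ciliated"),
                                each = n_per_group), names(seqs))
  alignment_set(seqs, groups, "cil1")
}
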