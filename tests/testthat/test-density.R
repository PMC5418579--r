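test_that("a single atom renders with conserved integral and correct peak", {
  g <- simulate_density(single_atom("C", pos = c(1, 2, 3)), 8, 2)
  expect_equal(sum(g$values), 6, tolerance = 1e-3)      # carbon weight, 0.1%
  pk <- which(g$values == max(g$values), arr.ind = TRUE)[1, ]
  world <- g$origin + g$voxel * c(pk[3] - 1, pk[2] - 1, pk[1] - 1)
  expect_lt(max(abs(world - c(1, 2, 3))), g$voxel)      # within one voxel
  expect_error(simulate_density(single_atom(), resolution = 3, voxel_size = 2),
               "undersampled")
})

test_that("density simulation is linear in the model", {
  a <- single_atom("C", c(0, 0, 0))
  b <- single_atom("O", c(6, 2, -3))
  b$atoms$chain <- "B"
  ab <- merge_models(a, b)
  geom <- simulate_density(ab, 8, 2)
  ga <- simulate_density(a, 8, 2, grid = geom)
  gb <- simulate_density(b, 8, 2, grid = geom)
  gab <- simulate_density(ab, 8, 2, grid = geom)
  expect_lt(max(abs(gab$values - (ga$values + gb$values))), 1e-6)
  # doubling identical atoms doubles the integral
  a2 <- a
  a2$atoms <- rbind(a$atoms, transform(a$atoms, serial = 2, resno = 2))
  a2 <- structure_model(a2$atoms)
  expect_equal(sum(simulate_density(a2, 8, 2)$values),
               2 * sum(ga$values), tolerance = 1e-3)
})

test_that("compiled rendering matches an independent untruncated oracle", {
  m <- build_singlet(lattice_spec(13, n_repeats = 1, open_arc = 5))
  g <- simulate_density(m, resolution = 12, voxel_size = 4)
  o <- brute_density(m, resolution = 12, g)
  expect_gt(real_space_cc(g, o), 0.99)
  expect_lt(max(abs(g$values - o$values)), 1e-3 * max(o$values))
})

test_that("real-space correlation has the expected fixed points", {
  g <- simulate_density(template_monomer("alpha"), 8, 2)
  expect_equal(real_space_cc(g, g), 1.0)
  neg <- density_grid(-g$values, g$voxel, g$origin)
  expect_equal(real_space_cc(g, neg), -1.0)
  flat <- density_grid(array(1, dim(g$values)), g$voxel, g$origin)
  expect_error(real_space_cc(g, flat), "zero variance")
  small <- density_grid(array(0, c(2, 2, 2)), 2)
  expect_error(real_space_cc(g, small), "shape")
})

test_that("noise attenuates the correlation as 1/sqrt(1 + sigma^2/s^2)", {
  g <- simulate_density(build_singlet(lattice_spec(13, n_repeats = 1)),
                        resolution = 16, voxel_size = 4)
  s <- sd(g$values)
  ccs <- vapply(1:5, function(seed) {
    real_space_cc(add_noise(g, s, seed), g)
  }, numeric(1))
  expect_equal(mean(ccs), 1 / sqrt(2), tolerance = 0.05)
})

test_that("voxel-size calibration is self-consistent and fixes a mislabel", {
  tm <- template_monomer("alpha")
  emap <- simulate_density(tm, resolution = 6, voxel_size = 1.375)
  self <- calibrate_voxel_size(emap, tm, resolution = 6)
  expect_equal(self$scale, 1.0, tolerance = 1e-3)
  # the map really has 1.375 A voxels but is labelled 1.395
  mislabelled <- density_grid(emap$values, 1.395, emap$origin / 1.375 * 1.395)
  cal <- calibrate_voxel_size(mislabelled, tm, resolution = 6)
  expect_equal(cal$voxel_size, 1.375, tolerance = 0.002)
  flat <- density_grid(array(0, dim(emap$values)), 1.395, emap$origin)
  expect_error(calibrate_voxel_size(flat, tm, resolution = 6), "zero variance")
})

test_that("difference maps vanish identically and absorb affine scaling", {
  g <- simulate_density(template_monomer("alpha"), 8, 2)
  d0 <- difference_map(g, g)
  expect_lt(max(abs(d0$values)), 1e-10)
  aff <- density_grid(2 * g$values + 5, g$voxel, g$origin)
  d1 <- difference_map(aff, g)
  expect_lt(max(abs(d1$values)), 1e-9)
})

test_that("planted MIP densities are recovered in the difference map", {
  m <- build_singlet(lattice_spec(13))
  sim <- simulate_density(m, resolution = 16, voxel_size = 4)
  amp <- 1.5 * max(sim$values)
  planted <- plant_mips(sim, list(
    list(type = "blob", center = c(0, 0, 80), sigma = 8, amplitude = amp),
    list(type = "filament", p0 = c(95, 35, 20), p1 = c(95, 35, 140),
         sigma = 5, amplitude = amp)))
  dm <- difference_map(planted$grid, sim)
  recovered <- mean(dm$values[planted$mask] >= 0.5 * amp)
  expect_gte(recovered, 0.9)
  false_pos <- mean(dm$values[!planted$mask] >= 0.5 * amp)
  expect_lte(false_pos, 0.01)
})

test_that("register assignment is perfect on a noiseless doublet map", {
  d <- build_doublet()
  a <- assign_pfs(d)
  emap <- simulate_density(d, resolution = 20, voxel_size = 4)
  ra <- assign_alpha_beta_register(emap, d, a, resolution = 20)
  expect_equal(nrow(ra), 23)
  expect_true(all(ra$register == "register-0"))
  expect_false(any(ra$ambiguous))
})

test_that("register assignment survives noise at half the signal level", {
  d <- build_doublet()
  a <- assign_pfs(d)
  emap <- simulate_density(d, resolution = 20, voxel_size = 4)
  s <- sd(emap$values[emap$values > 0.05 * max(emap$values)])
  correct <- 0; total <- 0
  for (seed in 1:20) {
    noisy <- add_noise(emap, 0.5 * s, seed)
    ra <- assign_alpha_beta_register(noisy, d, a, resolution = 20)
    correct <- correct + sum(ra$register == "register-0")
    total <- total + nrow(ra)
  }
  expect_gte(correct / total, 0.9)
})

test_that("a symmetric template gives ambiguous register calls", {
  # alpha == beta: shifting by one monomer leaves the lattice density unchanged
  tm <- template_monomer("alpha")
  same <- list(alpha = tm, beta = tm)
  m <- build_singlet(lattice_spec(13, n_repeats = 2), template = same)
  a <- assign_pfs(m)
  emap <- simulate_density(m, resolution = 20, voxel_size = 4)
  ra <- assign_alpha_beta_register(emap, m, a, resolution = 20, tie_tol = 0.02)
  expect_gt(mean(ra$ambiguous), 0.8)
  expect_lt(max(ra$confidence), 0.05)
})

test_that("identity-transform subvolumes equal raw crops", {
  vals <- array(rnorm(24^3), c(24, 24, 24))
  g <- density_grid(vals, 2, c(0, 0, 0))
  ctr <- c(23, 23, 23)            # voxel (11.5, 11.5, 11.5) in index space
  sv <- extract_subvolumes(g, ctr, box_size = 9)
  expect_length(sv$volumes, 1)
  # centre voxel of the box must equal trilinear at the centre point
  centre_val <- sv$volumes[[1]]$values[5, 5, 5]
  expect_equal(centre_val,
               mean(vals[12:13, 12:13, 12:13]), tolerance = 1e-9)
  expect_error(extract_subvolumes(g, ctr, box_size = 40), "box larger")
  expect_warning(extract_subvolumes(g, c(2, 2, 2), box_size = 9), "outside")
})

test_that("a rotated copy resamples back onto the template faithfully", {
  tm <- template_monomer("alpha")
  g <- simulate_density(tm, resolution = 10, voxel_size = 2, pad = 14)
  R <- rotation_about_axis(c(0, 0, 1), 35)
  rot_model <- apply_transform(rigid_transform(R), tm)
  g_rot <- simulate_density(rot_model, resolution = 10, voxel_size = 2,
                            grid = density_grid(array(0, dim(g$values) + 20),
                                                2, g$origin - 20))
  sv <- extract_subvolumes(g_rot, centers = matrix(0, 1, 3),
                           transforms = list(rigid_transform(R)),
                           box_size = 25)
  ref <- extract_subvolumes(g, centers = matrix(0, 1, 3), box_size = 25)
  expect_gt(real_space_cc(sv$volumes[[1]], ref$volumes[[1]]), 0.98)
})

test_that("one subvolume per dimer comes out of a doublet map", {
  d <- build_doublet()
  a <- assign_pfs(d)
  emap <- simulate_density(d, resolution = 20, voxel_size = 4, pad = 30)
  df <- a$chains
  keys <- unique(paste(df$tubule, df$pf, df$dimer))
  centers <- t(vapply(keys, function(k) {
    ch <- df$chain[paste(df$tubule, df$pf, df$dimer) == k]
    colMeans(coords(select_atoms(d, chain = ch)))
  }, numeric(3)))
  sv <- extract_subvolumes(emap, centers, box_size = 15)
  expect_length(sv$volumes, nrow(centers))
  expect_equal(nrow(centers), 46)       # (13 + 10) PFs x 2 dimers
})

test_that("averaging identical subvolumes reproduces the input exactly", {
  g <- simulate_density(template_monomer("alpha"), 10, 2)
  sv <- extract_subvolumes(g, rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)),
                           box_size = 11)
  avg <- average_subvolumes(sv)
  expect_equal(avg$values, sv$volumes[[1]]$values, tolerance = 1e-12)
  expect_error(average_subvolumes(extract_subvolumes(g, c(0, 0, 0),
                                                     box_size = 11)),
               "at least 2")
})

test_that("averaging N noisy copies shrinks background noise as 1/sqrt(N)", {
  base <- density_grid(array(0, c(20, 20, 20)), 2)
  for (N in c(4, 16)) {
    vols <- lapply(seq_len(N), function(s) add_noise(base, 1, s))
    sv <- structure(list(volumes = vols,
                         transforms = replicate(N, rigid_transform(),
                                                simplify = FALSE),
                         labels = paste0("s", seq_len(N)),
                         box_size = 20, voxel = 2), class = "subvolume_set")
    avg <- average_subvolumes(sv)
    expect_equal(sd(avg$values), 1 / sqrt(N), tolerance = 0.1)
  }
})

test_that("averaging variance reduction passes a chi-squared check over seeds", {
  # variance of the mean of N iid N(0,1) voxels is 1/N: pooled over 50 seeds
  # the scaled sum of squares is chi-squared with m degrees of freedom
  N <- 8
  m_vox <- 12^3
  stat <- 0
  for (seed in 1:50) {
    base <- density_grid(array(0, c(12, 12, 12)), 2)
    vols <- lapply(seq_len(N), function(s) add_noise(base, 1, 1000 * seed + s))
    avg <- Reduce(`+`, lapply(vols, `[[`, "values")) / N
    stat <- stat + sum(avg^2) * N       # ~ chi2(m_vox) per seed
  }
  df <- 50 * m_vox
  # two-sided 5% bounds via normal approximation of the chi-squared
  expect_gt(stat, df - 3 * sqrt(2 * df))
  expect_lt(stat, df + 3 * sqrt(2 * df))
})

test_that("correlation to the noiseless template rises monotonically with N", {
  g <- simulate_density(template_monomer("alpha"), 10, 2)
  sv0 <- extract_subvolumes(g, matrix(0, 1, 3), box_size = 13)
  template <- sv0$volumes[[1]]
  s <- sd(template$values)
  mean_cc <- vapply(c(2, 8, 32), function(N) {
    ccs <- vapply(1:20, function(seed) {
      vols <- lapply(seq_len(N), function(k) {
        add_noise(template, 2 * s, seed * 100 + k)
      })
      sv <- structure(list(volumes = vols,
                           transforms = replicate(N, rigid_transform(),
                                                  simplify = FALSE),
                           labels = paste0("s", seq_len(N)),
                           box_size = 13, voxel = 2), class = "subvolume_set")
      real_space_cc(average_subvolumes(sv), template)
    }, numeric(1))
    mean(ccs)
  }, numeric(1))
  expect_true(all(diff(mean_cc) > 0))
})

test_that("local refinement recovers a small misalignment", {
  g <- simulate_density(template_monomer("alpha"), 10, 2, pad = 16)
  ref <- extract_subvolumes(g, matrix(0, 1, 3), box_size = 17)$volumes[[1]]
  shifted <- extract_subvolumes(g, matrix(c(3, -2, 2), 1, 3),
                                box_size = 17)$volumes[[1]]
  sv <- structure(list(volumes = c(replicate(6, ref, simplify = FALSE),
                                   list(shifted)),
                       transforms = replicate(7, rigid_transform(),
                                              simplify = FALSE),
                       labels = paste0("s", 1:7), box_size = 17,
                       voxel = 2),
                  class = "subvolume_set")
  plain <- average_subvolumes(sv)
  refined <- average_subvolumes(sv, refine = TRUE)
  expect_gt(real_space_cc(refined, ref), real_space_cc(plain, ref))
})
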