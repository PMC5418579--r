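#' Plant synthetic MIP-like densities into a map
#'
#' Adds Gaussian blobs and/or Gaussian-cross-section cylindrical filaments to
#' a density grid, emulating globular and filamentous microtubule inner
#' proteins for difference-map testing. A ground-truth mask (voxels receiving
#' at least half of a descriptor's amplitude) is returned alongside.
#' Descriptors reaching outside the grid are clipped with a warning.
#'
#' Descriptor fields:
#' * blob: `list(type = "blob", center = c(x,y,z) A, sigma = A, amplitude)`
#' * filament: `list(type = "filament", p0 = c(x,y,z), p1 = c(x,y,z),
#'   sigma = A, amplitude, period = NULL)` -- optional axial periodicity in A
#'   (e.g. 80, 160, 480) modulates the amplitude as a raised cosine.
#'
#' @param grid density_grid
#' @param mips list of descriptors (empty list returns the grid unchanged)
#' @return list(grid = modified density_grid, mask = logical ground-truth
#'   array, added = array of added density)
#' @export
plant_mips <- function(grid, mips) {
  d <- grid_dims(grid)
  added <- array(0, dim = dim(grid$values))
  mask <- array(FALSE, dim = dim(grid$values))
  if (length(mips) == 0) {
    return(list(grid = grid, mask = mask, added = added))
  }
  ax <- grid$origin[1] + grid$voxel * (seq_len(d[1]) - 1)
  ay <- grid$origin[2] + grid$voxel * (seq_len(d[2]) - 1)
  az <- grid$origin[3] + grid$voxel * (seq_len(d[3]) - 1)
  for (mp in mips) {
    contrib <- array(0, dim = dim(grid$values))
    if (mp$type == "blob") {
      ctr <- mp$center
      if (any(ctr < grid$origin) ||
          any(ctr > grid$origin + grid$voxel * (d - 1))) {
        warning("blob centre outside grid; clipped")
      }
      gx <- exp(-(ax - ctr[1])^2 / (2 * mp$sigma^2))
      gy <- exp(-(ay - ctr[2])^2 / (2 * mp$sigma^2))
      gz <- exp(-(az - ctr[3])^2 / (2 * mp$sigma^2))
      # values array is (z, y, x)
      contrib <- mp$amplitude *
        outer(gz, outer(gy, gx, "*"), "*")
    } else if (mp$type == "filament") {
      u <- mp$p1 - mp$p0
      len <- sqrt(sum(u^2))
      u <- u / len
      # distance from each voxel to the segment p0-p1
      pts <- cbind(rep(ax, times = d[2] * d[3]),
                   rep(rep(ay, each = d[1]), times = d[3]),
                   rep(az, each = d[1] * d[2]))
      rel <- sweep(pts, 2, mp$p0)
      t_par <- as.numeric(rel %*% u)
      t_cl <- pmin(pmax(t_par, 0), len)
      perp2 <- rowSums((rel - outer(t_cl, u))^2)
      amp <- mp$amplitude * exp(-perp2 / (2 * mp$sigma^2))
      if (!is.null(mp$period)) {
        amp <- amp * (0.5 + 0.5 * cos(2 * pi * t_par / mp$period))
      }
      contrib <- aperm(array(amp, dim = d), c(3, 2, 1))
    } else {
      stop("unknown MIP descriptor type: ", mp$type)
    }
    added <- added + contrib
    mask <- mask | (contrib >= 0.5 * mp$amplitude)
  }
  list(grid = density_grid(grid$values + added, grid$voxel, grid$origin),
       mask = mask, added = added)
}

#' Add i.i.d. Gaussian noise to a density grid
#'
#' Reproducible given the seed; the caller's RNG state is untouched.
#'
#' @param grid density_grid
#' @param sigma noise standard deviation (>= 0)
#' @param seed integer
#' @return density_grid
#' @export
add_noise <- function(grid, sigma, seed) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(grid)
  noise <- with_seed(seed, stats::rnorm(length(grid$values), 0, sigma))
  density_grid(grid$values + array(noise, dim = dim(grid$values)),
               grid$voxel, grid$origin)
}
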