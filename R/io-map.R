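#' Density grid
#'
#' A 3-D scalar field with isotropic voxel size (Angstrom per voxel) and an
#' origin giving the world coordinate of the centre of voxel (0,0,0). The
#' values array is indexed `[z, y, x]` (dim = nz, ny, nx), so the world
#' coordinate of element `values[i, j, k]` is
#' `origin + voxel * c(k - 1, j - 1, i - 1)` on (x, y, z).
#'
#' @param values 3-D numeric array indexed (z, y, x)
#' @param voxel voxel size, Angstrom, isotropic, > 0
#' @param origin length-3 numeric (x, y, z), Angstrom
#' @return object of class `density_grid`
#' @export
density_grid <- function(values, voxel, origin = c(0, 0, 0)) {
  stopifnot(length(dim(values)) == 3, length(origin) == 3)
  if (!is.numeric(voxel) || length(voxel) != 1 || voxel <= 0) {
    stop("voxel size must be a single positive number")
  }
  if (!all(is.finite(values))) stop("non-finite density values")
  structure(list(values = values, voxel = voxel, origin = as.numeric(origin)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_grid: %d x %d x %d (nx,ny,nz), voxel %.4f A, origin (%.2f, %.2f, %.2f)\n",
              d[3], d[2], d[1], x$voxel, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Grid dimensions as (nx, ny, nz)
#' @param grid density_grid
#' @return integer vector length 3
#' @export
grid_dims <- function(grid) rev(dim(grid$values))

#' Read an MRC2014 density map
#'
#' The header axis permutation (mapc/mapr/maps) is applied so the returned
#' values array always follows the package (z, y, x) convention. Voxel size is
#' taken from the cell/grid header fields and must be isotropic; the origin
#' comes from the MRC2014 origin record, falling back to nstart * voxel.
#'
#' @param path file path to an MRC/CCP4 map
#' @return density_grid
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nc <- ints[1]; nr <- ints[2]; ns <- ints[3]; mode <- ints[4]
  nstart <- ints[5:7]
  m <- ints[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  invisible(readBin(con, "raw", n = 100))            # extra words 26-50
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  maptag <- rawToChar(readBin(con, "raw", n = 4))
  invisible(readBin(con, "raw", n = 1024 - 212))     # machst..labels
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  voxels <- cella / m
  if (diff(range(voxels)) > 1e-4 * mean(voxels)) {
    stop(sprintf("anisotropic voxels (%.4f, %.4f, %.4f A) are not supported",
                 voxels[1], voxels[2], voxels[3]))
  }
  nvox <- nc * nr * ns
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1, signed = TRUE,
                             endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    stop("unsupported MRC mode: ", mode))
  arr <- array(vals, dim = c(nc, nr, ns))       # axes (mapc, mapr, maps)
  arr <- aperm(arr, match(1:3, mapcrs))          # -> axes (x, y, z)
  arr <- aperm(arr, c(3, 2, 1))                  # -> (z, y, x) convention
  voxel <- mean(voxels)
  if (all(origin == 0) && any(nstart != 0)) {
    start_xyz <- numeric(3)
    start_xyz[mapcrs] <- nstart
    origin <- start_xyz * voxel
  }
  density_grid(arr, voxel, origin)
}

#' Write an MRC2014 density map (mode 2, 32-bit float)
#'
#' @param grid density_grid
#' @param path output path
#' @return invisibly, the path
#' @export
write_map <- function(grid, path) {
  d <- grid_dims(grid)                 # (nx, ny, nz)
  con <- file(path, "wb")
  on.exit(close(con))
  w_i <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_f <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  vals <- aperm(grid$values, c(3, 2, 1))   # (z,y,x) -> (x,y,z), x fastest
  w_i(d)                                   # nx ny nz
  w_i(2)                                   # mode 2 float
  w_i(c(0, 0, 0))                          # nstart
  w_i(d)                                   # mx my mz
  w_f(d * grid$voxel)                      # cella
  w_f(c(90, 90, 90))                       # cellb
  w_i(c(1, 2, 3))                          # mapc mapr maps
  w_f(c(min(grid$values), max(grid$values), mean(grid$values)))
  w_i(c(0, 0))                             # ispg, nsymbt
  writeBin(raw(100), con)                  # extra
  w_f(grid$origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  w_f(stats::sd(grid$values))
  w_i(0)                                   # nlabl
  writeBin(raw(800), con)
  writeBin(as.vector(vals), con, size = 4, endian = "little")
  invisible(path)
}
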