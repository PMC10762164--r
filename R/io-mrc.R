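#' Cryo-EM density map
#'
#' A `density_map` holds a 3D voxel grid in canonical (x, y, z) axis order
#' together with the voxel size and the position of the first voxel centre.
#'
#' @param grid 3D numeric array, >= 2 voxels along each axis
#' @param voxel_size voxel edge lengths, Angstrom (length 1 or 3, > 0)
#' @param origin coordinates of voxel (1,1,1), Angstrom (length 3)
#' @return object of class `density_map`
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L) stop("density_map: grid must be 3D")
  if (any(dim(grid) < 2L)) stop("density_map: need >= 2 voxels per axis")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) stop("density_map: voxel_size must be > 0")
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %s voxels @ %.3g x %.3g x %.3g A\n",
              paste(dim(x$grid), collapse = " x "),
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Read an MRC/CCP4 density map
#'
#' Supports MRC2014 mode-2 (32-bit float) maps, the format of EMDB
#' depositions. The grid is reindexed to canonical (x, y, z) order using
#' the MAPC/MAPR/MAPS header words; voxel size comes from the cell and
#' sampling header fields. The origin is taken from the ORIGIN header
#' words when set, else from NXSTART/NYSTART/NZSTART.
#'
#' @param path file path
#' @return a `density_map`
#' @export
read_density_map <- function(path) {
  if (!file.exists(path)) stop("read_density_map: no such file: ", path)
  sz <- file.info(path)$size
  if (sz < 1024) stop("read_density_map: corrupt header (file too small)")
  con <- file(path, "rb")
  on.exit(close(con))
  dims <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  nstart <- readBin(con, "integer", 3, size = 4, endian = "little")
  m <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  stats3 <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 4 * 49)
  orig <- readBin(con, "numeric", 3, size = 4, endian = "little")
  magic <- readChar(con, 4, useBytes = TRUE)
  if (any(dims <= 0) || any(dims > 1e5) || mode != 2L)
    stop("read_density_map: corrupt or unsupported header (mode ", mode,
         "); only MRC2014 mode-2 float maps are supported")
  if (!all(sort(mapcrs) == 1:3))
    stop("read_density_map: corrupt header: MAPC/MAPR/MAPS = ",
         paste(mapcrs, collapse = ","))
  nvox <- prod(dims)
  if (sz < 1024 + 4 * nvox)
    stop("read_density_map: truncated file: expected ", 1024 + 4 * nvox,
         " bytes, found ", sz)
  seek(con, 1024)
  vals <- readBin(con, "numeric", nvox, size = 4, endian = "little")
  arr <- array(vals, dim = dims)           # axes = (column, row, section)
  perm <- match(1:3, mapcrs)               # crystal axis j lives at perm[j]
  grid <- aperm(arr, perm)
  m_xyz <- ifelse(m > 0, m, dims[perm])
  voxel <- cella / m_xyz
  if (any(!is.finite(voxel)) || any(voxel <= 0)) voxel <- rep(1, 3)
  origin <- if (any(abs(orig) > 1e-6)) orig else nstart[perm] * voxel
  density_map(grid, voxel, origin)
}

#' Write a density map as MRC2014 (mode 2)
#'
#' @param map a `density_map`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  g <- map$grid
  d <- dim(g)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2L)                     # dims, mode 2
  wi(c(0L, 0L, 0L)); wi(d)          # nstart, sampling
  wf(d * map$voxel_size)            # cell lengths
  wf(c(90, 90, 90))                 # cell angles
  wi(1:3)                           # mapc, mapr, maps: canonical
  wf(c(min(g), max(g), mean(g)))    # dmin, dmax, dmean
  wi(c(1L, 0L))                     # ispg, nsymbt
  wi(rep(0L, 25))                   # extra (words 25-49)
  wf(map$origin)                    # MRC2014 origin
  writeChar("MAP ", con, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(as.vector(g)))       # rms
  wi(0L)                            # nlabl
  writeBin(raw(800), con)           # labels
  wf(as.vector(g))
  invisible(path)
}
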