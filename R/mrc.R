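# MRC2014 / CCP4 map I/O, mode 2 (32-bit float) only.  No R package in the
# dependency stack reads MRC, so the 1024-byte header is handled directly.

#' Read an MRC/CCP4 density map
#'
#' Supports MRC2014 mode-2 (float) maps on orthogonal cells.  The axis order
#' is normalized to x-fast using the `mapc`/`mapr`/`maps` header words, and
#' the origin is taken from the `origin` record when set, otherwise from
#' `nstart * voxel`.
#'
#' @param path file path
#' @return a [density_map()]
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", 10, size = 4, endian = "little")
  nxyz <- ints[1:3]; mode <- ints[4]; nstart <- ints[5:7]; mxyz <- ints[8:10]
  if (any(nxyz < 1) || any(nxyz > 4096)) stop("implausible MRC dimensions")
  if (mode != 2) stop("unsupported MRC mode ", mode, " (only mode 2 is handled)")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  if (max(abs(cellb - 90)) > 1e-3) stop("non-orthogonal cell angles are unsupported")
  readBin(con, "numeric", 3, size = 4, endian = "little")  # dmin dmax dmean
  readBin(con, "integer", 2, size = 4, endian = "little")  # ispg nsymbt
  readBin(con, "integer", 25, size = 4, endian = "little") # extra
  orig <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readChar(con, 4, useBytes = TRUE)                        # "MAP "
  readBin(con, "integer", 1, size = 4, endian = "little")  # machst
  readBin(con, "numeric", 1, size = 4, endian = "little")  # rms
  readBin(con, "integer", 1, size = 4, endian = "little")  # nlabl
  lab <- readChar(con, 80, useBytes = TRUE)
  seek(con, 1024)
  n <- prod(nxyz)
  vals <- readBin(con, "numeric", n, size = 4, endian = "little")
  if (length(vals) < n) stop("truncated MRC data block")
  arr <- array(vals, nxyz)  # column/row/section order as stored
  if (any(sort(mapcrs) != 1:3)) stop("invalid mapc/mapr/maps header")
  # permute storage axes (c, r, s) onto Cartesian (x, y, z)
  perm <- match(1:3, mapcrs)   # position of x, y, z among storage axes
  arr <- aperm(arr, perm)
  voxel <- cella / mxyz
  voxel_xyz <- voxel            # cella is in x,y,z order already
  ns_xyz <- nstart[perm]
  origin <- if (any(abs(orig) > 1e-6)) orig else ns_xyz * voxel_xyz
  density_map(arr, voxel_xyz, origin, label = trimws(lab))
}

#' Write a density map as an MRC2014 mode-2 file
#'
#' @param map a [density_map()]
#' @param path output path
#' @export
write_mrc <- function(map, path) {
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2); wi(c(0, 0, 0)); wi(d)
  wf(d * map$voxel); wf(c(90, 90, 90))
  wi(1:3)
  v <- as.vector(map$values)
  wf(c(min(v), max(v), mean(v)))
  wi(c(1, 0)); wi(rep(0L, 25))
  wf(map$origin)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian machine stamp
  wf(sd(v)); wi(1)
  lab <- sprintf("%-80s", substr(paste("cryofit:", map$label), 1, 80))
  writeChar(lab, con, 80, eos = NULL)
  writeChar(strrep(" ", 80 * 9), con, 80 * 9, eos = NULL)
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(NULL)
}
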