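#' Read an MRC/CCP4 density map
#'
#' Parses an MRC2014 file into a [density_grid()]. Only mode 2 (32-bit
#' float) maps are supported; other modes raise a format error naming the
#' offending header field. The data array is normalized on read to the
#' `(x, y, z)` fast-to-slow axis convention regardless of the header's
#' `MAPC/MAPR/MAPS` permutation, so voxel `(i, j, k)` always advances along
#' the crystal x, y and z axes respectively.
#'
#' The world origin is taken as `ORIGIN + NSTART * spacing` (both header
#' conventions honored; for maps written by this package `NSTART` is zero).
#'
#' @param path path to an MRC/CCP4 file.
#' @param map_kind map kind to tag the grid with (not stored in MRC headers).
#' @return A `density_grid`.
#' @export
read_map <- function(path, map_kind = "xray_diff") {
  if (!file.exists(path)) stop("cannot read map: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L) stop("format error: truncated MRC header")
  ints <- readBin(hdr_raw, "integer", n = 256L, size = 4L, endian = "little")
  flts <- readBin(hdr_raw, "double", n = 256L, size = 4L, endian = "little")
  nxyz <- ints[1:3]
  mode <- ints[4]
  if (mode != 2L)
    stop("format error: MODE = ", mode, "; only mode 2 (float32) maps are supported")
  if (any(nxyz < 1L)) stop("format error: non-positive NX/NY/NZ")
  nstart <- ints[5:7]
  mxyz <- ints[8:10]
  cella <- flts[11:13]
  mapcrs <- ints[17:19]
  if (!setequal(mapcrs, 1:3))
    stop("format error: MAPC/MAPR/MAPS must be a permutation of 1:3, got ",
         paste(mapcrs, collapse = ","))
  nsymbt <- ints[24]
  origin_hdr <- flts[50:52]
  if (any(mxyz < 1L)) stop("format error: non-positive MX/MY/MZ")
  spacing_xyz <- cella / mxyz          # sampling interval along crystal x,y,z
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  n <- prod(nxyz)
  vals <- readBin(con, "double", n = n, size = 4L, endian = "little")
  if (length(vals) != n) stop("format error: data section shorter than NX*NY*NZ")
  a <- array(vals, dim = nxyz)         # dims: (columns, rows, sections)
  # data axis j runs along crystal axis mapcrs[j]; permute to x,y,z order
  perm <- match(1:3, mapcrs)
  a <- aperm(a, perm)
  nstart_xyz <- nstart[perm]
  origin <- origin_hdr + nstart_xyz * spacing_xyz
  density_grid(a, origin = origin, spacing = spacing_xyz, map_kind = map_kind)
}

#' Write a density grid as an MRC map
#'
#' Writes an MRC2014 mode-2 (float32) file in the normalized axis convention
#' (`MAPC/MAPR/MAPS = 1,2,3`, `NSTART = 0`, origin in the `ORIGIN` header
#' words). [read_map()] of the result reproduces values, origin and spacing.
#'
#' @param grid a `density_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(grid, path) {
  stopifnot(is_density_grid(grid))
  d <- dim(grid$values)
  v <- as.numeric(grid$values)
  ints <- integer(256L)
  flts <- numeric(256L)
  ints[1:3] <- d
  ints[4] <- 2L
  ints[5:7] <- 0L
  ints[8:10] <- d
  flts[11:13] <- d * grid$spacing
  flts[14:16] <- 90
  ints[17:19] <- 1:3
  flts[20] <- min(v); flts[21] <- max(v); flts[22] <- mean(v)
  ints[23] <- 1L      # ISPG: P1
  ints[24] <- 0L      # NSYMBT
  flts[50:52] <- grid$origin
  flts[55] <- sd(v)
  ints[56] <- 0L      # NLABL
  word_is_float <- rep(FALSE, 256L)
  word_is_float[c(11:16, 20:22, 50:52, 55)] <- TRUE
  con <- file(path, "wb")
  on.exit(close(con))
  for (w in 1:256) {
    if (w == 53L) {
      writeBin(charToRaw("MAP "), con)                    # format magic
    } else if (w == 54L) {
      writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)    # LE machine stamp
    } else if (word_is_float[w]) {
      writeBin(flts[w], con, size = 4L, endian = "little")
    } else {
      writeBin(ints[w], con, size = 4L, endian = "little")
    }
  }
  writeBin(v, con, size = 4L, endian = "little")
  invisible(path)
}
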