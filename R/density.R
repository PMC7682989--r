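#' 3-D density grid
#'
#' Scalar cryo-EM density on a regular grid. `values[i, j, k]` sits at
#' Cartesian position `origin + (i-1, j-1, k-1) * voxel` (Angstrom), i.e. the
#' first array index runs along x, matching the common MRC axis order
#' (mapc/mapr/maps = 1/2/3).
#'
#' @param values 3-D numeric array.
#' @param voxel voxel size per axis in Angstrom (length 1 or 3).
#' @param origin Cartesian position of voxel (1,1,1), Angstrom.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(values, voxel, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3) stop("values must be a 3-D array")
  voxel <- rep(as.numeric(voxel), length.out = 3)
  if (any(voxel <= 0)) stop("voxel size must be > 0 on all axes")
  if (!all(is.finite(values))) stop("density values must be finite")
  structure(list(values = values, voxel = voxel,
                 origin = as.numeric(origin)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "density_grid %dx%dx%d, voxel %.3g/%.3g/%.3g A, origin (%g, %g, %g)\n",
    d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3],
    x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Read an MRC/CCP4 density map
#'
#' Minimal MRC2014 reader: supports modes 0 (int8), 1 (int16) and 2
#' (float32) with the standard column/row/section order. Voxel size is
#' cell / sampling; the origin is taken from the MRC2014 origin words, or
#' from `nxyzstart` when the origin words are zero.
#'
#' @param path MRC/CCP4 file.
#' @return A [density_grid].
#' @export
read_density <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  seek(con, 208)
  magic <- rawToChar(readBin(con, "raw", n = 4))
  if (substr(magic, 1, 3) != "MAP")
    stop("not an MRC2014 map (missing MAP magic): ", path)
  n <- hdr_int[1:3]
  mode <- hdr_int[4]
  if (!mode %in% c(0, 1, 2))
    stop("unsupported MRC mode ", mode, " in ", path)
  if (any(n <= 0)) stop("invalid grid dimensions in MRC header")
  nstart <- hdr_int[5:7]
  m <- hdr_int[8:10]
  cella <- hdr_num[11:13]
  mapc <- hdr_int[17]; mapr <- hdr_int[18]; maps <- hdr_int[19]
  nsymbt <- hdr_int[24]
  orig <- hdr_num[50:52]
  voxel <- ifelse(m > 0, cella / m, 1)
  nv <- prod(n)
  seek(con, 1024 + nsymbt)
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = nv, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = nv, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = nv, size = 4, endian = "little"))
  if (length(vals) < nv)
    stop("MRC payload shorter than header dimensions (",
         length(vals), " of ", nv, " voxels) in ", path)
  arr <- array(as.numeric(vals), dim = n)
  perm <- order(c(mapc, mapr, maps))
  if (!all(perm == 1:3)) arr <- aperm(arr, perm)
  if (all(orig == 0) && any(nstart != 0)) orig <- nstart * voxel
  density_grid(arr, voxel = voxel, origin = orig)
}

#' Write a density grid as an MRC2014 map
#'
#' Float32 (mode 2) with mapc/mapr/maps = 1/2/3; voxel values round-trip
#' exactly for data representable in single precision.
#'
#' @param grid a [density_grid].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_density <- function(grid, path) {
  d <- dim(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  v <- as.numeric(grid$values)
  wi(d)                           # nx ny nz
  wi(2)                           # mode float32
  wi(c(0, 0, 0))                  # nxyzstart
  wi(d)                           # mx my mz
  wf(d * grid$voxel)              # cell a b c
  wf(c(90, 90, 90))               # cell angles
  wi(c(1, 2, 3))                  # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))  # dmin dmax dmean
  wi(1)                           # ispg
  wi(0)                           # nsymbt
  wi(rep(0, 25))                  # extra (words 25-49)
  wf(grid$origin)                 # origin x y z (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(v))                       # rms
  wi(0)                           # nlabl
  writeBin(raw(800), con)         # labels
  wf(v)
  invisible(path)
}

# trilinear interpolation of a density_grid at Cartesian points (N x 3);
# points outside the grid evaluate to `outside`
interp_density <- function(grid, pts, outside = 0) {
  d <- dim(grid$values)
  g <- sweep(sweep(pts, 2, grid$origin), 2, grid$voxel, "/") + 1
  i0 <- floor(g)
  f <- g - i0
  ok <- i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
    i0[, 1] <= d[1] - 1 & i0[, 2] <= d[2] - 1 & i0[, 3] <= d[3] - 1
  out <- rep(outside, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  f <- f[ok, , drop = FALSE]
  V <- grid$values
  idx <- function(dx, dy, dz)
    V[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- idx(0, 0, 0) * (1 - fx) + idx(1, 0, 0) * fx
  c10 <- idx(0, 1, 0) * (1 - fx) + idx(1, 1, 0) * fx
  c01 <- idx(0, 0, 1) * (1 - fx) + idx(1, 0, 1) * fx
  c11 <- idx(0, 1, 1) * (1 - fx) + idx(1, 1, 1) * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

# Cartesian centers of all voxels, as a list of per-axis coordinate vectors
voxel_axes <- function(grid) {
  d <- dim(grid$values)
  lapply(1:3, function(a) grid$origin[a] + (seq_len(d[a]) - 1) * grid$voxel[a])
}
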