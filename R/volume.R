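#' Cubic density volume on a physical grid
#'
#' A `volume_grid` is a 3D numeric array carrying its voxel size in
#' Angstrom.  The third array index is the filament (z) axis; rotations
#' are right-handed about +z and the rotation centre is `(n-1)/2` along
#' each axis (0-based voxel coordinates).
#'
#' @param data 3D numeric array (nx x ny x nz).
#' @param pixel_A voxel edge length in Angstrom (> 0).
#' @return object of class `volume_grid`.
#' @export
volume_grid <- function(data, pixel_A) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  if (!is.numeric(pixel_A) || length(pixel_A) != 1L || pixel_A <= 0)
    stop("'pixel_A' must be a single positive number")
  structure(data, pixel_A = as.numeric(pixel_A),
            class = c("volume_grid", "array"))
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3f A/voxel (%.0f A box)\n",
              d[1], d[2], d[3], pixel_size(x), d[1] * pixel_size(x)))
  cat(sprintf("  density range [%.4g, %.4g], mean %.4g\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

#' Voxel or pixel size in Angstrom
#' @param x a `volume_grid` or any object with a `pixel_A` attribute.
#' @return numeric scalar, Angstrom.
#' @export
pixel_size <- function(x) {
  p <- attr(x, "pixel_A")
  if (is.null(p)) stop("object has no 'pixel_A' attribute")
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_volume_like <- function(data, template) {
  volume_grid(data, pixel_size(template))
}

## ---- spatial frequency helpers (unshifted FFT layout) ----

fft_freq <- function(n, d = 1) {
  # frequencies in cycles per unit of d, numpy fftfreq layout
  k <- c(0:(floor((n - 1) / 2)), -(ceiling((n - 1) / 2):1))
  k / (n * d)
}

freq_grid_2d <- function(n, pixel_A) {
  f <- fft_freq(n, pixel_A)
  fx <- matrix(f, n, n)
  fy <- matrix(f, n, n, byrow = TRUE)
  list(s = sqrt(fx^2 + fy^2), theta = atan2(fy, fx))
}

freq_grid_3d <- function(dims, pixel_A) {
  fx <- fft_freq(dims[1], pixel_A)
  fy <- fft_freq(dims[2], pixel_A)
  fz <- fft_freq(dims[3], pixel_A)
  sq <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  sqrt(sq)
}

## ---- MRC I/O (mode 2, little-endian) ----

#' Write a volume as an MRC map (mode 2, float32)
#'
#' Minimal MRC2014 writer: dimensions, cell size from the voxel size,
#' axis order x/y/z, density statistics and the MAP/machine-stamp
#' words.  Suitable for viewing in standard EM/graphics software.
#'
#' @param vol a `volume_grid` (or 2D matrix with `pixel_A` attribute).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path) {
  d <- dim(vol)
  if (length(d) == 2L) d <- c(d, 1L)
  px <- pixel_size(vol)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2 = float32
  wi(c(0L, 0L, 0L))          # nxstart
  wi(d)                      # mx my mz
  wf(d * px)                 # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1L, 2L, 3L))          # mapc mapr maps
  wf(c(min(vol), max(vol), mean(vol)))
  wi(c(1L, 0L))              # ispg, nsymbt
  wi(rep(0L, 25))            # extra
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(as.numeric(vol)))    # rms
  wi(0L)                     # nlabl
  writeBin(raw(800), con)    # empty labels
  wf(as.numeric(vol))
  invisible(path)
}

#' Read an MRC map written in mode 0, 1 or 2
#'
#' @param path MRC file.
#' @return a `volume_grid` (nz = 1 gives a one-slice volume).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)            # nxstart
  mx <- ri(3)
  cella <- rf(3)
  seek(con, 1024)
  n <- prod(d)
  dat <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "2" = rf(n),
    stop("unsupported MRC mode: ", mode))
  px <- if (mx[1] > 0 && cella[1] > 0) cella[1] / mx[1] else 1
  volume_grid(array(dat, dim = d), px)
}
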