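#' Contrast transfer function parameters
#'
#' Per-micrograph optics.  Defaults follow a 200 kV field-emission
#' microscope with 7% amplitude contrast.  By convention
#' `defocus_u_A >= defocus_v_A` (underfocus positive), with
#' `astig_angle_deg` the direction of the u axis.
#'
#' @param voltage_kV accelerating voltage, kV (> 0).
#' @param cs_mm spherical aberration, mm.
#' @param defocus_u_A,defocus_v_A defocus along the major/minor
#'   astigmatism axes, Angstrom.
#' @param astig_angle_deg angle of the defocus-u axis, degrees.
#' @param amp_contrast amplitude-contrast fraction in \[0, 1\].
#' @param pixel_A pixel size, Angstrom (> 0).
#' @return object of class `ctf_params`.
#' @export
ctf_params <- function(voltage_kV = 200, cs_mm = 2,
                       defocus_u_A = 15000, defocus_v_A = defocus_u_A,
                       astig_angle_deg = 0, amp_contrast = 0.07,
                       pixel_A = 1.35) {
  if (voltage_kV <= 0) stop("'voltage_kV' must be > 0")
  if (amp_contrast < 0 || amp_contrast > 1)
    stop("'amp_contrast' must be in [0, 1]")
  if (pixel_A <= 0) stop("'pixel_A' must be > 0")
  if (defocus_u_A < defocus_v_A)
    stop("'defocus_u_A' must be >= 'defocus_v_A'")
  structure(list(voltage_kV = voltage_kV, cs_mm = cs_mm,
                 defocus_u_A = defocus_u_A, defocus_v_A = defocus_v_A,
                 astig_angle_deg = astig_angle_deg,
                 amp_contrast = amp_contrast, pixel_A = pixel_A),
            class = "ctf_params")
}

#' @export
print.ctf_params <- function(x, ...) {
  cat(sprintf(paste0("<ctf_params> %g kV, Cs %g mm, defocus %g/%g A ",
                     "(astig %g deg), A %g, %g A/px\n"),
              x$voltage_kV, x$cs_mm, x$defocus_u_A, x$defocus_v_A,
              x$astig_angle_deg, x$amp_contrast, x$pixel_A)
  )
  invisible(x)
}

#' Relativistic electron wavelength
#' @param voltage_kV accelerating voltage, kV.
#' @return wavelength in Angstrom.
#' @export
electron_wavelength <- function(voltage_kV) {
  v <- voltage_kV * 1000
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Evaluate the CTF on a 2D Fourier grid
#'
#' `CTF(s, theta) = -(sqrt(1 - A^2) sin(chi) + A cos(chi))` with
#' `chi = pi * lambda * df(theta) * s^2 - (pi/2) * Cs * lambda^3 * s^4`
#' and `df(theta)` the astigmatic defocus.  The sign convention makes
#' the CTF negative at the origin (underfocus gives dark particles on a
#' bright background) and is used consistently by the simulator and the
#' correction, so the choice cancels in the pipeline.
#'
#' @param params a [ctf_params()].
#' @param n image side, pixels.
#' @return n x n matrix in unshifted FFT layout, values in \[-1, 1\].
#' @export
ctf_evaluate <- function(params, n) {
  stopifnot(inherits(params, "ctf_params"))
  if (params$pixel_A <= 0) stop("zero pixel size")
  g <- freq_grid_2d(n, params$pixel_A)
  lambda <- electron_wavelength(params$voltage_kV)
  cs <- params$cs_mm * 1e7                 # mm -> A
  df_avg <- (params$defocus_u_A + params$defocus_v_A) / 2
  df_dif <- (params$defocus_u_A - params$defocus_v_A) / 2
  df <- df_avg + df_dif * cos(2 * (g$theta - params$astig_angle_deg * pi / 180))
  chi <- pi * lambda * df * g$s^2 - (pi / 2) * cs * lambda^3 * g$s^4
  A <- params$amp_contrast
  out <- -(sqrt(1 - A^2) * sin(chi) + A * cos(chi))
  # the Nyquist row/column is its own conjugate partner: average the
  # two astigmatic evaluations so the filter stays Hermitian and
  # filtered images stay real
  if (n %% 2 == 0) {
    ny <- n / 2 + 1
    rev <- c(1, n:2)
    out[ny, ] <- (out[ny, ] + out[ny, rev]) / 2
    out[, ny] <- (out[, ny] + out[rev, ny]) / 2
  }
  out
}

#' Apply a CTF to an image by Fourier multiplication
#'
#' @param image square numeric matrix.
#' @param params a [ctf_params()].
#' @return filtered image (real matrix).
#' @export
apply_ctf <- function(image, params) {
  if (nrow(image) != ncol(image)) stop("non-square input")
  n <- nrow(image)
  ctf <- ctf_evaluate(params, n)
  out <- Re(fft(fft(image) * ctf, inverse = TRUE)) / (n * n)
  attributes(out) <- attributes(image)
  out
}

## ---- CTF^2 accumulation and Wiener-style restoration ----

#' Radial accumulator for per-shell sums of CTF^2
#'
#' Multiplying every segment by its CTF applies CTF^2 to the underlying
#' structure factor; the reconstruction is compensated at the end by
#' `1/[sum(CTF^2) + 1/SNR]`.  This object tracks the running shell sum.
#' Shells are 1D (rotationally averaged), one Fourier pixel wide on the
#' segment grid.
#'
#' @param n segment side, pixels.
#' @param pixel_A pixel size, Angstrom.
#' @return object of class `ctf2_accumulator`.
#' @export
ctf2_accumulator <- function(n, pixel_A) {
  nshell <- floor(n / 2) + 1L
  structure(list(n = n, pixel_A = pixel_A,
                 s = (seq_len(nshell) - 1) / (n * pixel_A),
                 sum_ctf2 = numeric(nshell),
                 count = 0L),
            class = "ctf2_accumulator")
}

#' @rdname ctf2_accumulator
#' @param acc a `ctf2_accumulator`.
#' @param ctf_mat an n x n CTF matrix from [ctf_evaluate()], or a
#'   `ctf_params` object.
#' @export
accumulate_ctf2 <- function(acc, ctf_mat) {
  stopifnot(inherits(acc, "ctf2_accumulator"))
  if (inherits(ctf_mat, "ctf_params")) ctf_mat <- ctf_evaluate(ctf_mat, acc$n)
  g <- freq_grid_2d(acc$n, acc$pixel_A)
  shell <- as.integer(pmin(round(g$s * acc$n * acc$pixel_A),
                           length(acc$s) - 1L)) + 1L
  sums <- rowsum(as.numeric(ctf_mat^2), shell)
  cnts <- tabulate(shell, nbins = length(acc$s))
  idx <- as.integer(rownames(sums))
  mean_shell <- numeric(length(acc$s))
  mean_shell[idx] <- sums[, 1] / pmax(cnts[idx], 1L)
  acc$sum_ctf2 <- acc$sum_ctf2 + mean_shell
  acc$count <- acc$count + 1L
  acc
}

#' @export
print.ctf2_accumulator <- function(x, ...) {
  cat(sprintf("<ctf2_accumulator> %d segments, %d shells to %.3g 1/A\n",
              x$count, length(x$s), max(x$s)))
  invisible(x)
}

#' Wiener-style amplitude restoration
#'
#' Scales each Fourier shell of the reconstruction by
#' `1/[sum(CTF^2) + 1/SNR]`, compensating the amplitude distortion that
#' CTF-multiplied segments accumulate.  The shell-summed CTF^2 is
#' interpolated onto the volume's 3D frequency magnitudes.
#'
#' @param volume a `volume_grid`.
#' @param acc a populated [ctf2_accumulator()].
#' @param snr assumed spectral signal-to-noise ratio (> 0, default
#'   0.05).
#' @return restored `volume_grid`.
#' @export
wiener_restore <- function(volume, acc, snr = 0.05) {
  stopifnot(inherits(acc, "ctf2_accumulator"))
  if (acc$count < 1L) stop("empty accumulator")
  if (snr <= 0) stop("'snr' must be > 0")
  s3 <- freq_grid_3d(dim(volume), pixel_size(volume))
  sum2 <- approx(acc$s, acc$sum_ctf2, xout = pmin(s3, max(acc$s)),
                 rule = 2)$y
  fac <- 1 / (sum2 + 1 / snr)
  f <- fft(unclass(volume)) * array(fac, dim = dim(volume))
  out <- Re(fft(f, inverse = TRUE)) / prod(dim(volume))
  as_volume_like(out, volume)
}

## ---- band-pass and B-factor filters ----

soft_edge_weights <- function(s, high_pass_A, low_pass_A, n, pixel_A,
                              edge_px = 5) {
  w <- rep(1, length(s))
  dw <- edge_px / (n * pixel_A)      # transition width in 1/A
  if (!is.null(high_pass_A)) {
    fc <- 1 / high_pass_A
    # keep the transition above fc/2 so the DC term and frequencies
    # well below the cutoff are removed completely even in small boxes
    tw <- min(dw, fc / 2)
    lo <- fc - tw
    w[s < lo] <- 0
    i <- s >= lo & s < fc
    w[i] <- 0.5 * (1 - cos(pi * (s[i] - lo) / tw))
  }
  if (!is.null(low_pass_A)) {
    fc <- 1 / low_pass_A
    hi <- fc + dw
    i <- s > fc & s < hi
    w[i] <- w[i] * 0.5 * (1 + cos(pi * (s[i] - fc) / dw))
    w[s >= hi] <- 0
  }
  w
}

#' Band-pass filter an image or volume
#'
#' Soft (raised-cosine) high- and/or low-pass in Fourier space.  Cutoffs
#' are given as real-space lengths in Angstrom; the transition is
#' `edge_px` Fourier pixels wide (clamped so a high-pass always removes
#' the DC term completely).  Shell energy is never increased.
#'
#' @param x square matrix with a `pixel_A` attribute, or `volume_grid`.
#' @param high_pass_A,low_pass_A cutoff lengths in Angstrom, or `NULL`.
#' @param pixel_A pixel size; defaults to `attr(x, "pixel_A")`.
#' @param edge_px transition width in Fourier pixels.
#' @return filtered object of the same kind.
#' @export
bandpass <- function(x, high_pass_A = NULL, low_pass_A = NULL,
                     pixel_A = NULL, edge_px = 5) {
  pixel_A <- pixel_A %||% attr(x, "pixel_A")
  if (is.null(pixel_A)) stop("pixel size unknown; supply 'pixel_A'")
  if (!is.null(high_pass_A) && !is.null(low_pass_A) &&
      high_pass_A < low_pass_A)
    stop("high-pass cutoff is finer than low-pass cutoff")
  d <- dim(x)
  n <- d[1]
  s <- if (length(d) == 2L) freq_grid_2d(n, pixel_A)$s
       else freq_grid_3d(d, pixel_A)
  w <- array(soft_edge_weights(as.numeric(s), high_pass_A, low_pass_A,
                               n, pixel_A, edge_px), dim = d)
  out <- Re(fft(fft(unclass(x)) * w, inverse = TRUE)) / prod(d)
  attributes(out) <- attributes(x)
  out
}

#' B-factor sharpening / damping
#'
#' Multiplies Fourier amplitudes by `exp(-B s^2 / 4)`; a negative B
#' (e.g. -200 A^2) amplifies high spatial frequencies.
#'
#' @param volume a `volume_grid` (or matrix with `pixel_A`).
#' @param b_factor_A2 signed B factor, Angstrom^2.
#' @return filtered object of the same kind.
#' @export
sharpen_bfactor <- function(volume, b_factor_A2) {
  pixel_A <- attr(volume, "pixel_A")
  d <- dim(volume)
  s <- if (length(d) == 2L) freq_grid_2d(d[1], pixel_A)$s
       else freq_grid_3d(d, pixel_A)
  w <- exp(-b_factor_A2 * s^2 / 4)
  out <- Re(fft(fft(unclass(volume)) * array(w, dim = d),
                inverse = TRUE)) / prod(d)
  attributes(out) <- attributes(volume)
  out
}
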