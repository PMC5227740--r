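#' Pseudo-atom model of one helical asymmetric unit
#'
#' A small set of 3D Gaussian blobs standing in for one actin+myosin
#' repeat.  Blob positions are in Angstrom in the frame of subunit 0
#' (z along the filament axis); `radius_A` declares the outer radius of
#' the filament that all blobs must respect.
#'
#' @param blobs data.frame with columns `x`, `y`, `z` (A), `weight`,
#'   `width_A` (Gaussian sigma, A, > 0).
#' @param radius_A declared outer filament radius, Angstrom.
#' @return object of class `pseudo_atom_model`.
#' @export
pseudo_atom_model <- function(blobs, radius_A = 150) {
  need <- c("x", "y", "z", "weight", "width_A")
  if (!all(need %in% names(blobs))) stop("blobs needs columns: ",
                                         paste(need, collapse = ", "))
  if (nrow(blobs) < 1L) stop("at least one blob required")
  if (any(blobs$width_A <= 0)) stop("all blob widths must be > 0")
  r <- sqrt(blobs$x^2 + blobs$y^2)
  if (any(r > radius_A))
    stop("blob radial distance exceeds declared filament radius")
  structure(list(blobs = blobs, radius_A = radius_A),
            class = "pseudo_atom_model")
}

#' Default asymmetric unit emulating an actin+myosin repeat footprint
#'
#' Seven blobs: a compact core near the axis (the actin strand) and an
#' elongated outer lobe (the bound myosin head) reaching ~140 A radius.
#' The arrangement is chiral and azimuthally asymmetric so projections
#' carry orientation and polarity information.
#'
#' @param radius_A declared outer radius (default 150 A).
#' @return a `pseudo_atom_model`.
#' @export
default_asym_unit <- function(radius_A = 150) {
  blobs <- data.frame(
    x = c(14, -6, 4, 52, 88, 122, 30),
    y = c(2, 16, -12, 14, 26, 8, -26),
    z = c(0, 8, -6, 4, 10, 16, -10),
    weight = c(3, 2, 2, 2.5, 2, 1.5, 1.5),
    width_A = c(14, 12, 12, 16, 16, 14, 12)
  )
  pseudo_atom_model(blobs, radius_A = radius_A)
}

#' Build a helical filament density volume from an asymmetric unit
#'
#' Subunit k is placed by rotating the asymmetric unit by `k * twist`
#' about z and translating `k * rise` along z; the density is the sum
#' of all Gaussian blobs.  Subunits are centred on the box so the
#' interior is helically symmetric up to edge effects.
#'
#' @param asym_unit a [pseudo_atom_model()].
#' @param sym a [helical_symmetry()].
#' @param n_subunits number of subunits, or `NULL` to fill the whole
#'   axial extent of the box (plus one subunit of margin each side).
#' @param box_px cubic box side, voxels.
#' @param pixel_A voxel size, Angstrom.
#' @return a `volume_grid`.
#' @export
build_filament_volume <- function(asym_unit, sym, n_subunits = NULL,
                                  box_px = 96, pixel_A = 4) {
  stopifnot(inherits(asym_unit, "pseudo_atom_model"),
            inherits(sym, "helical_symmetry"))
  n <- box_px
  half_A <- (n - 1) / 2 * pixel_A
  wmax <- max(asym_unit$blobs$width_A)
  fill <- is.null(n_subunits)
  if (fill) {
    n_subunits <- 2L * ceiling(half_A / sym$rise_A) + 3L
  } else {
    if (n_subunits < 1) stop("'n_subunits' must be >= 1")
    zmax <- (n_subunits - 1) / 2 * sym$rise_A +
      max(abs(asym_unit$blobs$z)) + 3 * wmax
    if (zmax > half_A)
      stop(sprintf(paste0("grid too small along z: subunit stack needs ",
                          "%.0f A half-extent but box provides %.0f A"),
                   zmax, half_A))
    rmax <- max(sqrt(asym_unit$blobs$x^2 + asym_unit$blobs$y^2)) + 3 * wmax
    if (rmax > half_A)
      stop(sprintf(paste0("grid too small along x/y: blobs need %.0f A ",
                          "radius but box provides %.0f A"), rmax, half_A))
  }
  vol <- array(0, dim = c(n, n, n))
  ctr <- (n - 1) / 2
  ax <- (seq_len(n) - 1 - ctr) * pixel_A    # coordinates in A
  ks <- seq_len(n_subunits) - 1 - (n_subunits - 1) / 2
  for (k in ks) {
    ang <- k * sym$twist_deg * pi / 180
    ca <- cos(ang); sa <- sin(ang)
    dz <- k * sym$rise_A
    for (b in seq_len(nrow(asym_unit$blobs))) {
      bl <- asym_unit$blobs[b, ]
      bx <- ca * bl$x - sa * bl$y
      by <- sa * bl$x + ca * bl$y
      bz <- bl$z + dz
      w <- bl$width_A
      # local support window (+- 3.5 sigma)
      ix <- which(abs(ax - bx) <= 3.5 * w)
      iy <- which(abs(ax - by) <= 3.5 * w)
      iz <- which(abs(ax - bz) <= 3.5 * w)
      if (!length(ix) || !length(iy) || !length(iz)) next
      gx <- exp(-(ax[ix] - bx)^2 / (2 * w^2))
      gy <- exp(-(ax[iy] - by)^2 / (2 * w^2))
      gz <- exp(-(ax[iz] - bz)^2 / (2 * w^2))
      vol[ix, iy, iz] <- vol[ix, iy, iz, drop = FALSE] +
        bl$weight * (gx %o% gy %o% gz)
    }
  }
  volume_grid(vol, pixel_A)
}

#' Simulate boxed filament segments with recorded ground truth
#'
#' Each segment is a projection of `vol` at a uniform random azimuth
#' and a uniform out-of-plane tilt within `tilt_limit_deg`, shifted by
#' sub-pixel offsets, rotated in-plane, multiplied by an astigmatic CTF
#' in Fourier space, and degraded with additive white Gaussian noise of
#' standard deviation `noise_sigma` times the CTF-modulated signal RMS.
#' Filament polarity is assigned per filament; polarity -1 segments are
#' rotated by an extra 180 degrees in plane.  All truths and CTF
#' parameters are recorded in the metadata.
#'
#' @param vol filament `volume_grid`.
#' @param n_filaments,segs_per_filament counts (>= 1).
#' @param defocus_range_A sampling interval for the mean defocus
#'   (default 10000-20000 A, i.e. 1.0-2.0 um underfocus).
#' @param noise_sigma noise level as a fraction of signal RMS (>= 0).
#' @param tilt_limit_deg out-of-plane tilt sampling half-range.
#' @param inplane_limit_deg in-plane rotation sampling half-range.
#' @param shift_limit_px sub-pixel shift sampling half-range.
#' @param voltage_kV,cs_mm,amp_contrast,astig_frac microscope optics;
#'   `astig_frac` is the fractional defocus difference (u - v)/mean.
#' @param seed RNG seed (mandatory, for reproducibility).
#' @return a `segment_set`: list with `images` (n x n x S array),
#'   `meta` (one row per segment), `pixel_A` and shared optics fields.
#' @export
simulate_segments <- function(vol, n_filaments, segs_per_filament,
                              defocus_range_A = c(10000, 20000),
                              noise_sigma = 1,
                              tilt_limit_deg = 10,
                              inplane_limit_deg = 4,
                              shift_limit_px = 2,
                              voltage_kV = 200, cs_mm = 2,
                              amp_contrast = 0.07, astig_frac = 0.04,
                              seed) {
  if (n_filaments < 1 || segs_per_filament < 1)
    stop("counts must be positive")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  n <- dim(vol)[1]
  px <- pixel_size(vol)
  S <- n_filaments * segs_per_filament
  images <- array(0, dim = c(n, n, S))
  meta <- vector("list", S)
  s <- 0L
  for (f in seq_len(n_filaments)) {
    polarity <- sample(c(1L, -1L), 1L)
    df_mean <- runif(1, defocus_range_A[1], defocus_range_A[2])
    df_half <- df_mean * astig_frac / 2
    defu <- df_mean + df_half
    defv <- df_mean - df_half
    astig <- runif(1, 0, 180)
    ctf <- ctf_params(voltage_kV = voltage_kV, cs_mm = cs_mm,
                      defocus_u_A = defu, defocus_v_A = defv,
                      astig_angle_deg = astig,
                      amp_contrast = amp_contrast, pixel_A = px)
    ctf_mat <- ctf_evaluate(ctf, n)
    for (i in seq_len(segs_per_filament)) {
      s <- s + 1L
      azi <- runif(1, 0, 360)
      tilt <- if (tilt_limit_deg > 0)
        runif(1, -tilt_limit_deg, tilt_limit_deg) else 0
      psi <- if (inplane_limit_deg > 0)
        runif(1, -inplane_limit_deg, inplane_limit_deg) else 0
      dx <- if (shift_limit_px > 0)
        runif(1, -shift_limit_px, shift_limit_px) else 0
      dy <- if (shift_limit_px > 0)
        runif(1, -shift_limit_px, shift_limit_px) else 0
      proj <- project_volume_cpp(unclass(vol), azi, tilt)
      psi_eff <- psi + if (polarity < 0) 180 else 0
      img <- rotate_shift_image_cpp(proj, psi_eff, dx, dy)
      img <- Re(fft(fft(img) * ctf_mat, inverse = TRUE)) / (n * n)
      if (noise_sigma > 0) {
        sig_rms <- sd(as.numeric(img))
        img <- img + rnorm(n * n, sd = noise_sigma * sig_rms)
      }
      images[, , s] <- img
      meta[[s]] <- data.frame(
        filament_id = f, index = i,
        true_azimuth_deg = azi, true_tilt_deg = tilt,
        true_inplane_deg = psi, true_dx_px = dx, true_dy_px = dy,
        true_polarity = polarity,
        defocus_u_A = defu, defocus_v_A = defv, astig_angle_deg = astig)
    }
  }
  segment_set(images, do.call(rbind, meta), pixel_A = px,
              voltage_kV = voltage_kV, cs_mm = cs_mm,
              amp_contrast = amp_contrast)
}

#' Container for boxed segment images plus per-segment metadata
#'
#' @param images n x n x S numeric array.
#' @param meta data.frame with one row per segment; must contain
#'   `filament_id` and `index`.
#' @param pixel_A pixel size, Angstrom.
#' @param voltage_kV,cs_mm,amp_contrast shared microscope optics.
#' @param preprocessed has [preprocess_segments()] been applied?
#' @return object of class `segment_set`.
#' @export
segment_set <- function(images, meta, pixel_A, voltage_kV = 200,
                        cs_mm = 2, amp_contrast = 0.07,
                        preprocessed = FALSE) {
  stopifnot(length(dim(images)) == 3L, nrow(meta) == dim(images)[3])
  stopifnot(all(c("filament_id", "index") %in% names(meta)))
  structure(list(images = images, meta = meta, pixel_A = pixel_A,
                 voltage_kV = voltage_kV, cs_mm = cs_mm,
                 amp_contrast = amp_contrast,
                 preprocessed = preprocessed),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<segment_set> %d segments of %d x %d px (%.2f A/px), %d filaments%s\n",
              d[3], d[1], d[2], x$pixel_A,
              length(unique(x$meta$filament_id)),
              if (isTRUE(x$preprocessed)) ", preprocessed" else ""))
  invisible(x)
}

#' @export
length.segment_set <- function(x) dim(x$images)[3]

#' CTF parameters of one segment of a set
#' @param segs a `segment_set`.
#' @param i segment index.
#' @return a [ctf_params()] object.
#' @export
segment_ctf <- function(segs, i) {
  m <- segs$meta[i, ]
  ctf_params(voltage_kV = segs$voltage_kV, cs_mm = segs$cs_mm,
             defocus_u_A = m$defocus_u_A, defocus_v_A = m$defocus_v_A,
             astig_angle_deg = m$astig_angle_deg,
             amp_contrast = segs$amp_contrast, pixel_A = segs$pixel_A)
}

#' Write / read a segment set as an MRC stack plus a metadata table
#'
#' `<prefix>.mrc` holds the image stack (one z-slice per segment) and
#' `<prefix>.tsv` the tab-separated metadata (one row per segment).
#'
#' @param segs a `segment_set`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_segment_set <- function(segs, prefix) {
  write_mrc(volume_grid(segs$images, segs$pixel_A),
            paste0(prefix, ".mrc"))
  meta <- segs$meta
  meta$voltage_kV <- segs$voltage_kV
  meta$cs_mm <- segs$cs_mm
  meta$amp_contrast <- segs$amp_contrast
  meta$preprocessed <- segs$preprocessed
  write.table(meta, paste0(prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_segment_set
#' @export
read_segment_set <- function(prefix) {
  vol <- read_mrc(paste0(prefix, ".mrc"))
  meta <- read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE)
  images <- unclass(vol)
  attributes(images) <- list(dim = dim(images))
  segment_set(images, meta[setdiff(names(meta),
                c("voltage_kV", "cs_mm", "amp_contrast", "preprocessed"))],
              pixel_A = pixel_size(vol),
              voltage_kV = meta$voltage_kV[1], cs_mm = meta$cs_mm[1],
              amp_contrast = meta$amp_contrast[1],
              preprocessed = isTRUE(meta$preprocessed[1]))
}
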