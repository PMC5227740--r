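#' Reference projection label grid
#'
#' One (azimuth, tilt) pair per reference view: azimuth covers
#' \[0, 360) in `azimuth_step_deg` increments and out-of-plane tilt
#' covers `[-tilt_limit_deg, +tilt_limit_deg]` in `tilt_step_deg`
#' increments, giving `(360/azimuth_step) * (2*tilt_limit/tilt_step + 1)`
#' views (15,120 at the production sampling of 0.5 degrees azimuth and
#' +-10/1 degrees tilt).
#'
#' @param azimuth_step_deg azimuthal sampling step; must divide 360.
#' @param tilt_limit_deg out-of-plane tilt half-range (0 = no tilt).
#' @param tilt_step_deg tilt sampling step; must divide `2*tilt_limit`.
#' @return data.frame with columns `azimuth_deg`, `tilt_deg`.
#' @export
reference_grid <- function(azimuth_step_deg, tilt_limit_deg = 0,
                           tilt_step_deg = 1) {
  if (azimuth_step_deg <= 0 || 360 %% azimuth_step_deg != 0)
    stop("'azimuth_step_deg' must divide 360 evenly")
  if (tilt_limit_deg < 0) stop("'tilt_limit_deg' must be >= 0")
  if (tilt_limit_deg > 0 &&
      (tilt_step_deg <= 0 ||
       abs((2 * tilt_limit_deg) %% tilt_step_deg) > 1e-9))
    stop("'tilt_step_deg' must divide the tilt range evenly")
  azi <- seq(0, 360 - azimuth_step_deg, by = azimuth_step_deg)
  tilt <- if (tilt_limit_deg > 0)
    seq(-tilt_limit_deg, tilt_limit_deg, by = tilt_step_deg) else 0
  expand.grid(azimuth_deg = azi, tilt_deg = tilt,
              KEEP.OUT.ATTRS = FALSE)
}

#' Generate reference projections of a 3D reference volume
#'
#' Projects the volume at every (azimuth, tilt) of [reference_grid()].
#' When `ctf` is supplied the references are CTF-multiplied so they
#' match preprocessed (CTF-applied) segments; a group-averaged CTF
#' matrix from [average_ctf()] is accepted as well as single
#' [ctf_params()].
#'
#' @param volume a `volume_grid`.
#' @inheritParams reference_grid
#' @param ctf `NULL`, a [ctf_params()], or an n x n CTF matrix.
#' @return object of class `reference_set`: `images` (n x n x R),
#'   `labels` (the grid), `pixel_A`, `source_signature`.
#' @export
make_reference_projections <- function(volume, azimuth_step_deg,
                                       tilt_limit_deg = 0,
                                       tilt_step_deg = 1, ctf = NULL) {
  labels <- reference_grid(azimuth_step_deg, tilt_limit_deg, tilt_step_deg)
  n <- dim(volume)[1]
  R <- nrow(labels)
  ctf_mat <- NULL
  if (!is.null(ctf)) {
    ctf_mat <- if (inherits(ctf, "ctf_params")) ctf_evaluate(ctf, n) else ctf
    stopifnot(all(dim(ctf_mat) == c(n, n)))
  }
  images <- array(0, dim = c(n, n, R))
  for (r in seq_len(R)) {
    img <- project_volume_cpp(unclass(volume), labels$azimuth_deg[r],
                              labels$tilt_deg[r])
    if (!is.null(ctf_mat))
      img <- Re(fft(fft(img) * ctf_mat, inverse = TRUE)) / (n * n)
    images[, , r] <- img
  }
  structure(list(images = images, labels = labels,
                 pixel_A = pixel_size(volume),
                 source_signature = sprintf("%dx%dx%d/%.6g/%.6g",
                                            dim(volume)[1], dim(volume)[2],
                                            dim(volume)[3], sum(volume),
                                            sum(volume^2))),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d projections of %d x %d px (%.2f A/px)\n",
              nrow(x$labels), dim(x$images)[1], dim(x$images)[2],
              x$pixel_A))
  invisible(x)
}

#' In-plane rotation search grid
#'
#' Candidate in-plane angles spanning `+-inplane_limit_deg` in
#' `inplane_step_deg` increments; with `include_flip` the grid is
#' duplicated at +180 degrees so both filament polarities are searched.
#'
#' @param inplane_limit_deg half-range, degrees (0 = just 0).
#' @param inplane_step_deg grid step, degrees.
#' @param include_flip include the flipped-polarity branch?
#' @return numeric vector of angles in degrees.
#' @export
default_psis <- function(inplane_limit_deg, inplane_step_deg,
                         include_flip = TRUE) {
  psis <- if (inplane_limit_deg > 0)
    seq(-inplane_limit_deg, inplane_limit_deg, by = inplane_step_deg)
  else 0
  if (include_flip) psis <- c(psis, psis + 180)
  psis
}

#' Align segments against a reference set by projection matching
#'
#' Every segment is compared (normalised cross-correlation, cyclic
#' translation search via FFT) against each candidate reference at each
#' candidate in-plane rotation; the best (reference, in-plane, shift)
#' triple wins.  Ties break to the smallest (|tilt|, shift magnitude,
#' azimuth).  In-plane angles offset by 180 degrees represent the
#' flipped filament polarity; the winning branch sets `polarity`.
#' Shifts are reported in the canonical (un-rotated) segment frame.
#'
#' @param segs a preprocessed `segment_set`.
#' @param refs a `reference_set` on the same grid.
#' @param shift_limit_px translation search half-range, pixels.
#' @param psis in-plane rotation candidates, degrees (see
#'   [default_psis()]).
#' @param candidates integer matrix (segments x K) of reference indices
#'   to evaluate per segment, or `NULL` for all references.
#' @return data.frame of alignment records: `filament_id`, `index`,
#'   `in_plane_deg`, `x_shift_px`, `y_shift_px`, `azimuth_deg`,
#'   `tilt_deg`, `cc`, `kept`, `polarity`.
#' @export
align_segments <- function(segs, refs, shift_limit_px = 5,
                           psis = default_psis(4, 2),
                           candidates = NULL) {
  stopifnot(inherits(segs, "segment_set"), inherits(refs, "reference_set"))
  if (dim(segs$images)[1] != dim(refs$images)[1])
    stop("segments and references are on different grids")
  R <- nrow(refs$labels)
  if (R < 1L) stop("empty reference set")
  S <- length(segs)
  if (is.null(candidates))
    candidates <- matrix(seq_len(R), nrow = S, ncol = R, byrow = TRUE)
  if (!is.matrix(psis))
    psis <- matrix(psis, nrow = S, ncol = length(psis), byrow = TRUE)
  res <- align_batch_cpp(segs$images, refs$images,
                         refs$labels$azimuth_deg, refs$labels$tilt_deg,
                         psis, as.integer(shift_limit_px),
                         candidates)
  ri <- res[, 1]
  psi <- res[, 2] %% 360
  data.frame(filament_id = segs$meta$filament_id,
             index = segs$meta$index,
             in_plane_deg = psi,
             x_shift_px = res[, 3], y_shift_px = res[, 4],
             azimuth_deg = refs$labels$azimuth_deg[ri],
             tilt_deg = refs$labels$tilt_deg[ri],
             cc = res[, 5],
             kept = TRUE,
             polarity = ifelse(psi > 90 & psi <= 270, -1L, 1L))
}

#' Align one segment
#'
#' Convenience wrapper around [align_segments()] for a single image.
#'
#' @param segment square numeric matrix.
#' @param refs a `reference_set`.
#' @inheritParams align_segments
#' @return a one-row alignment record.
#' @export
align_segment <- function(segment, refs, shift_limit_px = 5,
                          psis = default_psis(4, 2)) {
  segs <- segment_set(array(segment, dim = c(dim(segment), 1L)),
                      data.frame(filament_id = 1L, index = 1L),
                      pixel_A = refs$pixel_A, preprocessed = TRUE)
  align_segments(segs, refs, shift_limit_px, psis)
}

#' Discard records with small cross-correlation
#'
#' @param records alignment records from [align_segments()].
#' @param mode `"percentile"` (threshold from the current cc
#'   distribution) or `"absolute"`.
#' @param value percentile in \[0, 100\] or an absolute cc threshold.
#' @return records with updated `kept` flags (`cc >= threshold`).
#' @export
filter_by_cc <- function(records, mode = c("percentile", "absolute"),
                         value = 10) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) stop("no alignment records")
  thr <- if (mode == "percentile") {
    if (value < 0 || value > 100) stop("percentile outside [0, 100]")
    as.numeric(quantile(records$cc, value / 100))
  } else value
  keep <- records$cc >= thr
  n_drop <- sum(records$kept & !keep)
  records$kept <- records$kept & keep
  message(sprintf("cc filter (%s %.4g): discarded %d of %d records",
                  mode, value, n_drop, nrow(records)))
  records
}

#' Resolve per-filament polarity by majority vote
#'
#' The orientation of each filament is defined as that of the majority
#' of its (kept) segments; minority segments are discarded.  An exact
#' tie discards the whole filament.
#'
#' @param records alignment records with `polarity` evidence.
#' @return records with minority/tied segments un-kept.
#' @export
resolve_polarity <- function(records) {
  for (f in unique(records$filament_id)) {
    i <- which(records$filament_id == f & records$kept)
    if (!length(i)) next
    up <- sum(records$polarity[i] > 0)
    down <- length(i) - up
    if (up == down) {
      records$kept[records$filament_id == f] <- FALSE
      message(sprintf("filament %s: polarity tie (%d/%d), discarded", f,
                      up, down))
    } else {
      maj <- if (up > down) 1L else -1L
      records$kept[i[records$polarity[i] != maj]] <- FALSE
    }
  }
  records
}
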