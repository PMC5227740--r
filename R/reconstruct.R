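#' Featureless solid cylinder as an unbiased initial reference
#'
#' Density 1 inside the radius and 0 outside, with a 2-voxel cosine
#' edge; the standard model-bias-free starting volume for helical
#' refinement (200 Angstrom diameter by default).
#'
#' @param diameter_A cylinder diameter, Angstrom.
#' @param box_px cubic box side, voxels.
#' @param pixel_A voxel size, Angstrom.
#' @return a `volume_grid`.
#' @export
make_initial_cylinder <- function(diameter_A = 200, box_px = 96,
                                  pixel_A = 4) {
  if (diameter_A > box_px * pixel_A)
    stop("cylinder diameter exceeds the box")
  n <- box_px
  ctr <- (n - 1) / 2
  ax <- (seq_len(n) - 1 - ctr) * pixel_A
  r <- sqrt(outer(ax^2, ax^2, `+`))
  R <- diameter_A / 2
  e <- 2 * pixel_A
  disc <- ifelse(r <= R - e, 1,
                 ifelse(r >= R, 0, 0.5 * (1 + cos(pi * (r - (R - e)) / e))))
  volume_grid(array(disc, dim = c(n, n, n)), pixel_A)
}

## ---- weighted back-projection ----

# move one aligned segment to its canonical frame (undo in-plane
# rotation and shifts) and apply the in-plane r-weight |s_x|
canonical_segment <- function(img, psi, sx, sy) {
  a <- psi * pi / 180
  dr <- c(cos(a) * sx - sin(a) * sy, sin(a) * sx + cos(a) * sy)
  out <- rotate_shift_image_cpp(img, -psi, -dr[1], -dr[2])
  n <- nrow(out)
  w <- matrix(abs(fft_freq(n)), n, n)     # ramp along x (rows)
  Re(fft(fft(out) * w, inverse = TRUE)) / (n * n)
}

backproject_sums <- function(segs, records) {
  keep <- which(records$kept)
  if (!length(keep)) stop("no kept segments to backproject")
  n <- dim(segs$images)[1]
  canon <- array(0, dim = c(n, n, length(keep)))
  for (i in seq_along(keep)) {
    k <- keep[i]
    canon[, , i] <- canonical_segment(segs$images[, , k],
                                      records$in_plane_deg[k],
                                      records$x_shift_px[k],
                                      records$y_shift_px[k])
  }
  backproject_cpp(canon, records$azimuth_deg[keep],
                  records$tilt_deg[keep], c(n, n, n))
}

finish_backprojection <- function(bp, pixel_A) {
  out <- bp$sum
  w <- bp$weight
  out[w > 0] <- out[w > 0] / w[w > 0]
  volume_grid(out, pixel_A)
}

#' Weighted back-projection of aligned segments
#'
#' Each kept segment is moved to its canonical frame (in-plane rotation
#' and shifts removed), r-weighted by `|s_x|` (the in-plane frequency
#' perpendicular to the filament axis), and smeared into the volume
#' along its (azimuth, tilt) viewing direction.  Voxels are normalised
#' by their per-voxel contribution counts, so duplicating segments
#' leaves the result unchanged.
#'
#' @param segs a preprocessed `segment_set`.
#' @param records alignment records; only `kept` rows contribute.
#' @return a `volume_grid` (cubic, same side as the segments).
#' @export
backproject <- function(segs, records) {
  finish_backprojection(backproject_sums(segs, records), segs$pixel_A)
}

## ---- helical symmetry search and imposition ----

symmetry_mask <- function(dims, pixel_A, radius_A = NULL, z_frac = 0.5) {
  n <- dims[1]
  ctr <- (n - 1) / 2
  ax <- (seq_len(n) - 1 - ctr) * pixel_A
  if (is.null(radius_A)) radius_A <- 0.45 * n * pixel_A
  disc <- outer(ax^2, ax^2, `+`) <= radius_A^2
  nz <- dims[3]
  zc <- (nz - 1) / 2
  zi <- abs(seq_len(nz) - 1 - zc) <= z_frac * nz / 2
  outer(disc, zi, `&`)
}

symmetry_residual <- function(vol, twist_deg, rise_A, mask) {
  rs <- resample_volume_cpp(unclass(vol), twist_deg,
                            rise_A / pixel_size(vol))
  ok <- (rs$weight > 0) & mask
  mean((vol[ok] - rs$values[ok])^2)
}

parabolic_min <- function(xs, ys, i) {
  # refine grid minimum at index i by a 3-point parabola (clamped)
  if (i == 1L || i == length(xs)) return(xs[i])
  d <- (ys[i - 1] - 2 * ys[i] + ys[i + 1])
  if (d <= 0) return(xs[i])
  unname(xs[i] + 0.5 * (ys[i - 1] - ys[i + 1]) / d * (xs[i + 1] - xs[i]))
}

#' Determine helical symmetry by least squares
#'
#' Finds the (twist, rise) minimising the mean squared difference,
#' within a cylindrical mask, between the volume and its copy rotated
#' by twist and shifted axially by rise: a grid search over the given
#' windows followed by parabolic refinement of the minimum.  The
#' residual surface is returned for diagnostics.  The twist window must
#' not span both branch aliases (half-width < 90 degrees).
#'
#' @param volume a `volume_grid`.
#' @param twist_centre_deg,twist_halfwidth_deg,twist_step_deg twist
#'   search window, degrees.
#' @param rise_centre_A,rise_halfwidth_A,rise_step_A rise search
#'   window, Angstrom.
#' @param mask_radius_A cylindrical mask radius (default 45% of the
#'   box); only the central `z_frac` of the axial extent is compared.
#' @param z_frac axial fraction of the box used for the fit.
#' @param flat_eps degeneracy threshold: relative depth of the residual
#'   surface below this raises a degenerate-symmetry error.
#' @return list with `sym` (a [helical_symmetry()]), `residuals`
#'   (twist x rise matrix with dimnames), and `grid_min`.
#' @export
fit_helical_symmetry <- function(volume, twist_centre_deg,
                                 twist_halfwidth_deg = 5,
                                 twist_step_deg = 1,
                                 rise_centre_A, rise_halfwidth_A = 2,
                                 rise_step_A = 0.4,
                                 mask_radius_A = NULL, z_frac = 0.5,
                                 flat_eps = 1e-3) {
  if (twist_halfwidth_deg >= 90)
    stop("twist window half-width must be < 90 degrees (branch aliasing)")
  if (twist_step_deg <= 0 || rise_step_A <= 0) stop("steps must be > 0")
  mask <- symmetry_mask(dim(volume), pixel_size(volume), mask_radius_A,
                        z_frac)
  if (var(volume[mask]) == 0)
    stop("volume is degenerate (zero variance) within the mask")
  twists <- seq(twist_centre_deg - twist_halfwidth_deg,
                twist_centre_deg + twist_halfwidth_deg,
                by = twist_step_deg)
  rises <- seq(rise_centre_A - rise_halfwidth_A,
               rise_centre_A + rise_halfwidth_A, by = rise_step_A)
  if (any(rises <= 0)) stop("rise window must stay positive")
  res <- matrix(0, length(twists), length(rises),
                dimnames = list(sprintf("%.4f", twists),
                                sprintf("%.4f", rises)))
  for (i in seq_along(twists))
    for (j in seq_along(rises))
      res[i, j] <- symmetry_residual(volume, twists[i], rises[j], mask)
  # depth relative to the masked density variance: an azimuthally
  # featureless volume produces a residual surface orders of magnitude
  # shallower than any genuinely helical one
  depth <- (max(res) - min(res)) / max(var(volume[mask]),
                                       .Machine$double.eps)
  if (depth < flat_eps)
    stop("degenerate symmetry: residual surface is flat (relative depth ",
         signif(depth, 3), ")")
  ij <- which(res == min(res), arr.ind = TRUE)[1, ]
  t_ref <- parabolic_min(twists, res[, ij[2]], ij[1])
  r_ref <- parabolic_min(rises, res[ij[1], ], ij[2])
  # a minimum on the window boundary is not a located optimum
  on_edge <- ij[1] == 1L || ij[1] == length(twists) ||
    ij[2] == 1L || ij[2] == length(rises)
  list(sym = helical_symmetry(t_ref, r_ref), residuals = res,
       grid_min = c(twist_deg = twists[ij[1]], rise_A = rises[ij[2]]),
       on_edge = on_edge)
}

#' Impose helical symmetry on a volume
#'
#' Each voxel becomes the weight-normalised average of the volume
#' sampled at positions related by k * (twist, rise) for
#' k in -n_copies..+n_copies; samples falling outside the data support
#' simply drop out of the average.
#'
#' @param volume a `volume_grid`.
#' @param sym a [helical_symmetry()].
#' @param n_copies one-sided number of symmetry copies to average.
#' @return symmetrised `volume_grid`.
#' @export
impose_symmetry <- function(volume, sym, n_copies = 6) {
  stopifnot(inherits(sym, "helical_symmetry"), n_copies >= 1)
  px <- pixel_size(volume)
  acc <- array(0, dim = dim(volume))
  wt <- array(0, dim = dim(volume))
  for (k in -n_copies:n_copies) {
    rs <- resample_volume_cpp(unclass(volume), k * sym$twist_deg,
                              k * sym$rise_A / px)
    acc <- acc + rs$values
    wt <- wt + rs$weight
  }
  acc[wt > 0] <- acc[wt > 0] / wt[wt > 0]
  as_volume_like(acc, volume)
}

## ---- the IHRSR loop ----

#' Configuration for iterative helical real-space refinement
#'
#' Defaults follow the production protocol where it states parameters
#' (200 A initial cylinder, 285 A high-pass, FSC 0.5 per-cycle
#' low-pass, Wiener SNR, B-factor -200 A^2) at desk-scale sampling.
#'
#' @param initial_sym a [helical_symmetry()]: the symmetry imposed on
#'   the first reconstruction and the centre of the first search
#'   window (required; typically a perturbed guess).
#' @param twist_halfwidth_deg,twist_step_deg,rise_halfwidth_A,rise_step_A
#'   symmetry search window (centred on the current estimate).
#' @param azimuth_step_deg,tilt_limit_deg,tilt_step_deg reference
#'   projection sampling.
#' @param coarse_factor azimuth coarsening for the first (tilt-0)
#'   alignment pass; the second pass refines all tilts within the
#'   coarse neighbourhood.  1 = single exhaustive pass.
#' @param inplane_limit_deg,inplane_step_deg in-plane rotation search
#'   (both polarity branches are always included).
#' @param shift_limit_px translation search half-range.
#' @param cc_percentile cross-correlation discard percentile.
#' @param cylinder_diameter_A initial reference diameter.
#' @param snr Wiener restoration SNR.
#' @param b_factor_A2 final sharpening B factor.
#' @param final_lowpass_A final low-pass, or `NULL` to skip.
#' @param n_sym_copies symmetry-averaging copies.
#' @param max_cycles,tol_twist_deg,tol_rise_A convergence control:
#'   stop once at least five symmetry fits have been accepted and the
#'   spread (max minus min) of the last five fitted twists and rises
#'   stays within 1.5x the respective tolerance — a spread criterion
#'   over several fits registers a plateau but not a slow consistent
#'   drift, which a consecutive-delta rule mistakes for convergence.
#' @param fit_start_cycle earliest cycle at which the symmetry may be
#'   fitted; before that (and until the alignment stabilises) every
#'   cycle imposes the initial guess unchanged, letting the alignment
#'   lock onto helical features before the least squares takes over.
#' @param stability_threshold the symmetry fit engages once the
#'   fraction of segments whose azimuth assignment moved by at most
#'   two azimuth steps since the previous cycle stays at or above this
#'   value for two consecutive cycles (one brief plateau of a
#'   not-yet-locked alignment must not trigger fitting).
#' @param restart_cycle if the stability gate has not fired within
#'   this many cycles of a bootstrap phase, the bootstrap is restarted
#'   from the cylinder with a fresh seeded azimuth assignment (at most
#'   `max_restarts` times): a stalled partially-locked alignment does
#'   not improve with further cycles, but a different symmetry-breaking
#'   start usually locks.
#' @param max_restarts maximum number of bootstrap restarts.
#' @param fit_force_cycle phase cycle at which fitting starts
#'   regardless of the stability signal (only once no restarts
#'   remain; fits that hit the window edge are still rejected).
#' @param sym_fit_lowpass_A low-pass applied to the working map for
#'   the symmetry fit only: it must suppress reconstruction noise yet
#'   keep the subunit repeat resolved, so it should stay just below
#'   the expected rise.
#' @param first_cycle_azimuth `"align"` matches the first cycle against
#'   cylinder projections; `"random"` assigns uniform random azimuths
#'   (seeded), the usual symmetry-breaking start when the reference is
#'   featureless.
#' @param seed seed for `first_cycle_azimuth = "random"`.
#' @param verbose print one line per cycle.
#' @return a list of class `ihrsr_config`.
#' @export
ihrsr_config <- function(initial_sym,
                         twist_halfwidth_deg = 5, twist_step_deg = 1,
                         rise_halfwidth_A = 2, rise_step_A = 0.4,
                         azimuth_step_deg = 5, tilt_limit_deg = 10,
                         tilt_step_deg = 5, coarse_factor = 3,
                         inplane_limit_deg = 4, inplane_step_deg = 4,
                         shift_limit_px = 4, cc_percentile = 10,
                         cylinder_diameter_A = 200, snr = 0.05,
                         b_factor_A2 = -200, final_lowpass_A = NULL,
                         n_sym_copies = 6, max_cycles = 20,
                         tol_twist_deg = 0.2, tol_rise_A = 0.1,
                         fit_start_cycle = 5, stability_threshold = 0.9,
                         restart_cycle = 15, max_restarts = 1,
                         fit_force_cycle = 16, sym_fit_lowpass_A = 25,
                         first_cycle_azimuth = c("random", "align"),
                         seed = 1, verbose = TRUE) {
  stopifnot(inherits(initial_sym, "helical_symmetry"))
  cfg <- as.list(environment())
  cfg$first_cycle_azimuth <- match.arg(first_cycle_azimuth)
  class(cfg) <- "ihrsr_config"
  cfg
}

fsc_halves_by_parity <- function(segs, records) {
  # within-cycle even/odd filament split for the per-cycle FSC
  even <- records$filament_id %% 2 == 0
  a <- records; a$kept <- a$kept & even
  b <- records; b$kept <- b$kept & !even
  list(a = a, b = b)
}

#' Iterative helical real-space reconstruction (IHRSR)
#'
#' The full refinement loop: per cycle, project the current reference,
#' align every segment (five parameters + correlation), discard low-cc
#' segments, vote filament polarity, back-project, determine the
#' helical symmetry by least squares, impose it, and low-pass the new
#' reference at the cycle's FSC 0.5 resolution.  The loop starts from a
#' featureless solid cylinder; the initial symmetry guess is imposed on
#' the first reconstruction.  After convergence the map is
#' Wiener-restored with the accumulated CTF^2, B-factor sharpened, and
#' optionally low-passed.
#'
#' @param segs a preprocessed `segment_set` (with CTF^2 accumulator).
#' @param config an [ihrsr_config()].
#' @return an object of class `ihrsr`: `map` (final restored volume),
#'   `map_raw` (unrestored symmetrised volume), `sym` (converged
#'   [helical_symmetry()]), `trajectory` (one row per cycle),
#'   `records` (final alignment), `fsc` (final filament-split
#'   [fsc_curve()]), `resolution_A` (FSC 0.143), `converged`, `config`.
#' @export
ihrsr <- function(segs, config) {
  stopifnot(inherits(segs, "segment_set"), inherits(config, "ihrsr_config"))
  if (!isTRUE(segs$preprocessed))
    stop("segments must be preprocessed (see preprocess_segments)")
  n <- dim(segs$images)[1]
  px <- segs$pixel_A
  nyq <- 2 * px
  cfg <- config
  reference <- make_initial_cylinder(cfg$cylinder_diameter_A, n, px)
  ctf_mat <- average_ctf(segs, n, power = 2)
  sym <- cfg$initial_sym
  psis <- default_psis(cfg$inplane_limit_deg, cfg$inplane_step_deg)
  trajectory <- list()
  stable <- 0L
  converged <- FALSE
  records <- NULL
  full_raw <- NULL
  prev_azi <- NULL
  fit_enabled <- FALSE
  stab_run <- 0L
  restarts <- 0L
  phase_cycle <- 0L
  cycle <- 0L
  fitted_syms <- list()
  # the cycle budget grows only when a restart is actually taken
  while (cycle < cfg$max_cycles + restarts * cfg$restart_cycle) {
    cycle <- cycle + 1L
    phase_cycle <- phase_cycle + 1L
    # a bootstrap phase that never reached the stability gate is
    # stalled: restart it from the cylinder with a fresh seeded
    # azimuth assignment rather than burning the remaining cycles
    if (!fit_enabled && phase_cycle > cfg$restart_cycle &&
        restarts < cfg$max_restarts) {
      restarts <- restarts + 1L
      phase_cycle <- 1L
      reference <- make_initial_cylinder(cfg$cylinder_diameter_A, n, px)
      sym <- cfg$initial_sym
      prev_azi <- NULL
      stab_run <- 0L
      if (cfg$verbose)
        message(sprintf(
          "cycle %2d: alignment never locked, restarting bootstrap (%d)",
          cycle, restarts))
    }
    if (phase_cycle == 1L && cfg$first_cycle_azimuth == "random") {
      set.seed(cfg$seed + 1000L * restarts)
      S <- length(segs)
      records <- data.frame(
        filament_id = segs$meta$filament_id, index = segs$meta$index,
        in_plane_deg = sample(c(0, 180), S, replace = TRUE),
        x_shift_px = 0, y_shift_px = 0,
        azimuth_deg = runif(S, 0, 360), tilt_deg = 0,
        cc = 1, kept = TRUE, polarity = 1L)
      records$polarity <- ifelse(records$in_plane_deg > 90 &
                                   records$in_plane_deg <= 270, -1L, 1L)
    } else {
      refs <- make_reference_projections(reference, cfg$azimuth_step_deg,
                                         cfg$tilt_limit_deg,
                                         cfg$tilt_step_deg, ctf = ctf_mat)
      records <- align_two_stage(segs, refs, cfg, psis)
      records <- suppressMessages(
        filter_by_cc(records, "percentile", cfg$cc_percentile))
      records <- suppressMessages(resolve_polarity(records))
      if (!any(records$kept)) stop("all segments discarded in cycle ", cycle)
    }
    # alignment stability: fraction of segments whose azimuth moved
    # by <= 2 azimuth steps since the previous cycle
    stability <- if (is.null(prev_azi)) 0 else {
      d_az <- abs((records$azimuth_deg - prev_azi + 180) %% 360 - 180)
      mean(d_az <= 2 * cfg$azimuth_step_deg)
    }
    prev_azi <- records$azimuth_deg
    stab_run <- if (stability >= cfg$stability_threshold)
      stab_run + 1L else 0L
    if (!fit_enabled &&
        ((phase_cycle >= cfg$fit_start_cycle && stab_run >= 2L) ||
           (restarts >= cfg$max_restarts &&
              phase_cycle >= cfg$fit_force_cycle)))
      fit_enabled <- TRUE
    halves <- fsc_halves_by_parity(segs, records)
    bp_a <- backproject_sums(segs, halves$a)
    bp_b <- backproject_sums(segs, halves$b)
    vol_a <- finish_backprojection(bp_a, px)
    vol_b <- finish_backprojection(bp_b, px)
    full <- finish_backprojection(list(sum = bp_a$sum + bp_b$sum,
                                       weight = bp_a$weight + bp_b$weight),
                                  px)
    curve <- fsc_curve(vol_a, vol_b)
    res05 <- tryCatch(resolution_at(curve, 0.5),
                      error = function(e) 3 * nyq)
    # low-pass at the cycle's FSC 0.5 resolution for the next
    # reference, per the refinement protocol
    work <- bandpass(full, low_pass_A = max(res05, nyq))
    fit_accepted <- FALSE
    if (!fit_enabled) {
      new_sym <- sym
    } else {
      # the symmetry fit sees a map low-passed only to
      # sym_fit_lowpass_A: noise suppressed, subunit repeat kept;
      # search window stays centred on the initial guess
      fit_vol <- bandpass(full, low_pass_A = max(cfg$sym_fit_lowpass_A, nyq))
      fit <- fit_helical_symmetry(
        fit_vol, twist_centre_deg = cfg$initial_sym$twist_deg,
        twist_halfwidth_deg = cfg$twist_halfwidth_deg,
        twist_step_deg = cfg$twist_step_deg,
        rise_centre_A = cfg$initial_sym$rise_A,
        rise_halfwidth_A = cfg$rise_halfwidth_A,
        rise_step_A = cfg$rise_step_A)
      if (fit$on_edge) {
        # boundary minimum: not a located optimum, keep the current
        # symmetry for this cycle rather than imposing a window edge
        if (cfg$verbose)
          message(sprintf(
            "cycle %2d: symmetry fit hit the window edge, kept %s",
            cycle, format(sym)))
        new_sym <- sym
      } else {
        new_sym <- fit$sym
        fit_accepted <- TRUE
        fitted_syms[[length(fitted_syms) + 1L]] <- fit$sym
      }
    }
    full_raw <- impose_symmetry(full, new_sym, cfg$n_sym_copies)
    reference <- impose_symmetry(work, new_sym, cfg$n_sym_copies)
    d_t <- abs(new_sym$twist_deg - sym$twist_deg)
    d_r <- abs(new_sym$rise_A - sym$rise_A)
    trajectory[[cycle]] <- data.frame(
      cycle = cycle, phase_cycle = phase_cycle,
      twist_deg = new_sym$twist_deg,
      rise_A = new_sym$rise_A, fsc05_A = res05,
      stability = stability, fitted = fit_accepted,
      kept = sum(records$kept), discarded = sum(!records$kept))
    if (cfg$verbose)
      message(sprintf(
        "cycle %2d: twist %9.4f deg  rise %7.4f A  FSC0.5 %6.2f A  kept %d/%d",
        cycle, new_sym$twist_deg, new_sym$rise_A, res05,
        sum(records$kept), nrow(records)))
    sym <- new_sym
    if (length(fitted_syms) >= 5L) {
      t5 <- vapply(utils::tail(fitted_syms, 5), function(x) x$twist_deg, 0)
      r5 <- vapply(utils::tail(fitted_syms, 5), function(x) x$rise_A, 0)
      if (diff(range(t5)) < 1.5 * cfg$tol_twist_deg &&
          diff(range(r5)) < 1.5 * cfg$tol_rise_A) {
        converged <- TRUE
        break
      }
    }
  }
  # final estimate: average the last accepted fits to damp the
  # cycle-to-cycle wander of the least squares on noisy maps
  tail_fits <- utils::tail(fitted_syms, 3)
  if (length(tail_fits)) {
    sym <- helical_symmetry(
      mean(vapply(tail_fits, function(x) x$twist_deg, 0)),
      mean(vapply(tail_fits, function(x) x$rise_A, 0)))
    full_raw <- impose_symmetry(full, sym, cfg$n_sym_copies)
  }
  # final validation: filament-respecting balanced split
  halves <- split_halves_by_filament(records)
  vol_a <- impose_symmetry(backproject(segs, halves$a), sym,
                           cfg$n_sym_copies)
  vol_b <- impose_symmetry(backproject(segs, halves$b), sym,
                           cfg$n_sym_copies)
  final_fsc <- fsc_curve(vol_a, vol_b)
  res143 <- resolution_at(final_fsc, 0.143)
  map <- wiener_restore(full_raw, segs$ctf2_acc, cfg$snr)
  map <- sharpen_bfactor(map, cfg$b_factor_A2)
  if (!is.null(cfg$final_lowpass_A))
    map <- bandpass(map, low_pass_A = max(cfg$final_lowpass_A, nyq))
  structure(list(map = map, map_raw = full_raw, sym = sym,
                 trajectory = do.call(rbind, trajectory),
                 records = records, fsc = final_fsc,
                 resolution_A = res143, converged = converged,
                 config = cfg),
            class = "ihrsr")
}

align_two_stage <- function(segs, refs, cfg, psis) {
  lab <- refs$labels
  S <- length(segs)
  if (cfg$coarse_factor <= 1 || nrow(lab) <= 8) {
    return(align_segments(segs, refs, cfg$shift_limit_px, psis))
  }
  coarse_step <- cfg$azimuth_step_deg * cfg$coarse_factor
  stage1_idx <- which(lab$tilt_deg == 0 &
                        (lab$azimuth_deg %% coarse_step) == 0)
  cand1 <- matrix(stage1_idx, nrow = S, ncol = length(stage1_idx),
                  byrow = TRUE)
  # stage 1 decides coarse azimuth and polarity only
  rec1 <- align_segments(segs, refs, cfg$shift_limit_px, c(0, 180), cand1)
  # stage 2: all tilts within the coarse azimuth neighbourhood,
  # in-plane refined around the stage-1 winner
  lists <- vector("list", S)
  maxlen <- 0L
  for (s in seq_len(S)) {
    d_az <- abs((lab$azimuth_deg - rec1$azimuth_deg[s] + 180) %% 360 - 180)
    idx <- which(d_az <= coarse_step + 1e-9)
    lists[[s]] <- idx
    maxlen <- max(maxlen, length(idx))
  }
  cand2 <- t(vapply(lists, function(i) c(i, rep(i[1], maxlen - length(i))),
                    integer(maxlen)))
  # full in-plane grid within the winning polarity branch
  psi2 <- outer(rec1$in_plane_deg,
                seq(-cfg$inplane_limit_deg, cfg$inplane_limit_deg,
                    by = cfg$inplane_step_deg), `+`)
  align_segments(segs, refs, cfg$shift_limit_px, psi2, cand2)
}

#' @export
print.ihrsr <- function(x, ...) {
  cat("Iterative helical real-space reconstruction\n")
  cat(sprintf("  cycles run : %d (%s)\n", nrow(x$trajectory),
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  symmetry   : twist %.4f deg, rise %.4f A\n",
              x$sym$twist_deg, x$sym$rise_A))
  cat(sprintf("  resolution : %.2f A (FSC 0.143, filament-split halves)\n",
              x$resolution_A))
  cat(sprintf("  segments   : %d kept / %d total\n",
              sum(x$records$kept), nrow(x$records)))
  invisible(x)
}

#' @export
summary.ihrsr <- function(object, ...) {
  print(object)
  cat("\nRefinement trajectory:\n")
  print(object$trajectory, row.names = FALSE)
  invisible(object)
}

#' @export
coef.ihrsr <- function(object, ...) {
  c(twist_deg = object$sym$twist_deg, rise_A = object$sym$rise_A)
}

#' @export
plot.ihrsr <- function(x, ...) {
  op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  tr <- x$trajectory
  plot(tr$cycle, tr$twist_deg, type = "b", xlab = "cycle",
       ylab = "twist (deg)", main = "twist")
  plot(tr$cycle, tr$rise_A, type = "b", xlab = "cycle",
       ylab = "rise (A)", main = "rise")
  plot(x$fsc$s, x$fsc$fsc, type = "l", xlab = "spatial frequency (1/A)",
       ylab = "FSC", main = "final FSC", ylim = c(-0.1, 1))
  abline(h = c(0.5, 0.143), lty = 2, col = "grey50")
  invisible(x)
}

#' Write the refinement trajectory as a tab-separated log
#' @param fit an `ihrsr` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(fit, path) {
  write.table(fit$trajectory, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
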