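test_that("the initial cylinder has the declared geometry", {
  cyl <- make_initial_cylinder(200, 96, 4)
  ctr <- (96 - 1) / 2
  at_r <- function(rA) {
    i <- round(rA / 4 + ctr) + 1; j <- round(ctr) + 1
    cyl[i, j, 48]
  }
  expect_equal(at_r(90), 1)
  expect_equal(at_r(110), 0)
  expect_equal(at_r(-90), 1)
  expect_error(make_initial_cylinder(500, 96, 4), "exceeds")
  # azimuthally invariant; the cosine edge is 2 voxels wide, so the
  # trilinear resampling error there bounds the attainable agreement
  rot <- helixrec:::resample_volume_cpp(unclass(cyl), 33, 0)
  expect_lt(max(abs(rot$values[rot$weight > 0] - cyl[rot$weight > 0])),
            0.15 * max(cyl))
  expect_lt(mean(abs(rot$values[rot$weight > 0] - cyl[rot$weight > 0])),
            0.005 * max(cyl))
  # symmetry search on it is degenerate
  expect_error(fit_helical_symmetry(cyl, -166, 5, 1, 27.6, 2, 0.4),
               "degenerate")
})

test_that("back-projection inverts projection for dense angular sampling", {
  vol <- tiny_volume(n = 48)
  az <- seq(0, 359, by = 5)
  images <- array(0, c(48, 48, length(az)))
  for (i in seq_along(az))
    images[, , i] <- helixrec:::project_volume_cpp(unclass(vol), az[i], 0)
  segs <- segment_set(images, data.frame(filament_id = rep(1:2, 36),
                                         index = seq_along(az)),
                      pixel_A = 4, preprocessed = TRUE)
  rec <- data.frame(filament_id = segs$meta$filament_id,
                    index = segs$meta$index, in_plane_deg = 0,
                    x_shift_px = 0, y_shift_px = 0, azimuth_deg = az,
                    tilt_deg = 0, cc = 1, kept = TRUE, polarity = 1L)
  bp <- backproject(segs, rec)
  mask <- helixrec:::symmetry_mask(dim(vol), 4, 80, 0.6)
  expect_gt(cor(bp[mask], vol[mask]), 0.95)

  # duplicating every segment leaves the weighted result unchanged
  segs2 <- segment_set(array(rep(images, 2), c(48, 48, 2 * length(az))),
                       rbind(segs$meta, segs$meta), pixel_A = 4,
                       preprocessed = TRUE)
  bp2 <- backproject(segs2, rbind(rec, rec))
  expect_lt(max(abs(bp2 - bp)), 1e-8)
  expect_error(backproject(segs, transform(rec, kept = FALSE)), "kept")
})

test_that("a single segment back-projects to a smear along the beam", {
  blob <- array(0, c(32, 32, 32))
  blob[17, 17, 17] <- 1
  img <- helixrec:::project_volume_cpp(blob, 0, 0)
  segs <- segment_set(array(img, c(32, 32, 1)),
                      data.frame(filament_id = 1, index = 1),
                      pixel_A = 4, preprocessed = TRUE)
  rec <- data.frame(filament_id = 1, index = 1, in_plane_deg = 0,
                    x_shift_px = 0, y_shift_px = 0, azimuth_deg = 0,
                    tilt_deg = 0, cc = 1, kept = TRUE, polarity = 1L)
  bp <- backproject(segs, rec)
  # at azimuth 0 the projection direction is y: all y-slices identical
  for (j in 2:32) expect_lt(max(abs(bp[, j, ] - bp[, 1, ])), 1e-10)
})

test_that("helical symmetry fitting recovers the generating lattice", {
  sym <- actomyosin_sym()
  vol <- tiny_volume(sym, n = 64)
  fit <- fit_helical_symmetry(vol, twist_centre_deg = -165.2,
                              twist_halfwidth_deg = 5, twist_step_deg = 1,
                              rise_centre_A = 26.8, rise_halfwidth_A = 2,
                              rise_step_A = 0.4)
  expect_lt(abs(fit$sym$twist_deg - sym$twist_deg), 0.5)
  expect_lt(abs(fit$sym$rise_A - sym$rise_A), 0.3)
  # window guards
  expect_error(fit_helical_symmetry(vol, -165, 95, 1, 27, 2, 0.4), "branch")
  expect_error(fit_helical_symmetry(vol, -165, 5, 1, 1, 2, 0.4), "positive")
})

test_that("the grid stage equals an independent brute-force evaluation", {
  vol <- tiny_volume(n = 32)
  fit <- fit_helical_symmetry(vol, -166.67, 2, 1, 27.6, 1, 0.5,
                              z_frac = 0.5)
  mask <- helixrec:::symmetry_mask(dim(vol), 4, NULL, 0.5)
  twists <- as.numeric(rownames(fit$residuals))
  rises <- as.numeric(colnames(fit$residuals))
  for (i in seq_along(twists))
    for (j in seq_along(rises))
      expect_equal(fit$residuals[i, j],
                   r_sym_residual(vol, twists[i], rises[j], mask),
                   tolerance = 1e-10)
  expect_equal(unname(fit$grid_min),
               c(twists[which(fit$residuals == min(fit$residuals),
                              arr.ind = TRUE)[1, 1]],
                 rises[which(fit$residuals == min(fit$residuals),
                             arr.ind = TRUE)[1, 2]]))
})

test_that("mirroring the volume in z negates the fitted twist", {
  sym <- actomyosin_sym()
  vol <- tiny_volume(sym, n = 48)
  mir <- volume_grid(unclass(vol)[, , 48:1], 4)
  f <- fit_helical_symmetry(mir, -sym$twist_deg, 4, 0.5, sym$rise_A, 1.5,
                            0.3)
  expect_lt(abs(f$sym$twist_deg - (-sym$twist_deg)), 0.5)
  expect_lt(abs(f$sym$rise_A - sym$rise_A), 0.3)
})

test_that("symmetry imposition averages along the helical lattice", {
  sym <- actomyosin_sym()
  # near-idempotent on an already symmetric interior (2 A voxels keep
  # the interpolation error below the bound)
  vol <- build_filament_volume(tiny_asym(), sym, NULL, 96, 2)
  once <- impose_symmetry(vol, sym, 2)
  mask <- helixrec:::symmetry_mask(dim(vol), 2, 70, 0.4)
  expect_lt(sqrt(mean((once[mask] - vol[mask])^2)) / sd(vol[mask]), 0.0075)

  # twist 0, rise one voxel, one copy: the exact 3-point axial average
  set.seed(6)
  r <- volume_grid(array(rnorm(24^3), c(24, 24, 24)), 4)
  out <- impose_symmetry(r, helical_symmetry(0, 4), 1)
  n <- 24
  expected <- array(0, dim(r))
  for (k in 1:n) {
    ks <- intersect(c(k - 1, k, k + 1), 1:n)
    expected[, , k] <- apply(unclass(r)[, , ks, drop = FALSE], c(1, 2), mean)
  }
  expect_lt(max(abs(out - expected)), 1e-12)

  # imposing twice equals its own doubled-stencil expectation
  twice <- impose_symmetry(out, helical_symmetry(0, 4), 1)
  expected2 <- array(0, dim(r))
  for (k in 1:n) {
    ks <- intersect(c(k - 1, k, k + 1), 1:n)
    expected2[, , k] <- apply(unclass(out)[, , ks, drop = FALSE],
                              c(1, 2), mean)
  }
  expect_lt(max(abs(twice - expected2)), 1e-12)
})

test_that("imposing the fitted symmetry does not raise the fit residual", {
  vol <- tiny_volume(n = 32)
  mask <- helixrec:::symmetry_mask(dim(vol), 4, NULL, 0.4)
  fit <- fit_helical_symmetry(vol, -166.67, 2, 1, 27.6, 1, 0.5)
  before <- r_sym_residual(vol, fit$sym$twist_deg, fit$sym$rise_A, mask)
  sv <- impose_symmetry(vol, fit$sym, 4)
  after <- r_sym_residual(sv, fit$sym$twist_deg, fit$sym$rise_A, mask)
  expect_lte(after, before * 1.0001)
})

test_that("short refinements are deterministic and improve the map", {
  vol <- tiny_volume(n = 48)
  segs <- simulate_segments(vol, 8, 3, noise_sigma = 0.5,
                            tilt_limit_deg = 0, seed = 17)
  pre <- preprocess_segments(segs, 285, 40)
  cfg <- ihrsr_config(initial_sym = helical_symmetry(-166, 27.4),
                      tilt_limit_deg = 0, max_cycles = 3,
                      fit_start_cycle = 3, azimuth_step_deg = 6,
                      coarse_factor = 2, cylinder_diameter_A = 120,
                      verbose = FALSE, seed = 18)
  f1 <- expect_quiet(ihrsr(pre, cfg))
  f2 <- expect_quiet(ihrsr(pre, cfg))
  expect_identical(f1$trajectory, f2$trajectory)
  expect_identical(coef(f1), coef(f2))
  expect_s3_class(f1, "ihrsr")
  expect_equal(nrow(f1$trajectory), 3)
  expect_output(print(f1), "twist")
  expect_error(ihrsr(segs, cfg), "preprocessed")
})
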