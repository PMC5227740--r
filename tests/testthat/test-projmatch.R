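test_that("the reference grid enumerates (azimuth, tilt) views", {
  g <- reference_grid(0.5, 10, 1)
  expect_equal(nrow(g), 720 * 21)          # 15,120 at production sampling
  g4 <- reference_grid(90, 0)
  expect_equal(sort(g4$azimuth_deg), c(0, 90, 180, 270))
  expect_true(all(g4$tilt_deg == 0))
  expect_false(anyDuplicated(g) > 0)
  expect_error(reference_grid(7), "divide")
  expect_error(reference_grid(45, 10, 3), "divide")
})

test_that("projections of a coaxial cylinder are azimuth-independent", {
  cyl <- make_initial_cylinder(120, 48, 4)
  refs <- make_reference_projections(cyl, 45, 0, 1)
  base <- refs$images[, , 1]
  for (r in 2:dim(refs$images)[3]) {
    d <- abs(refs$images[, , r] - base)
    # grazing chords at the cosine edge set the worst-case trilinear
    # quadrature error; the bulk of the image agrees much tighter
    expect_lt(max(d), 0.05 * max(abs(base)))
    expect_lt(mean(d), 0.01 * mean(abs(base)))
  }
})

test_that("a segment that is a reference self-matches exactly", {
  vol <- tiny_volume(n = 48)
  refs <- make_reference_projections(vol, 10, 0, 1)
  seg <- refs$images[, , 5]
  rec <- align_segment(seg, refs, shift_limit_px = 3, psis = c(0, 180))
  expect_gte(rec$cc, 0.999)
  expect_equal(rec$x_shift_px, 0)
  expect_equal(rec$y_shift_px, 0)
  expect_equal(rec$azimuth_deg, refs$labels$azimuth_deg[5])
  expect_equal(rec$in_plane_deg, 0)
  expect_error(align_segments(
    segment_set(array(seg, c(48, 48, 1)),
                data.frame(filament_id = 1, index = 1), 4,
                preprocessed = TRUE),
    structure(list(images = array(0, c(48, 48, 0)),
                   labels = refs$labels[0, ], pixel_A = 4),
              class = "reference_set")), "empty")
})

test_that("alignment recovers a known transform and ignores image scale", {
  vol <- tiny_volume(n = 48)
  refs <- make_reference_projections(vol, 2, 0, 1)
  proj <- helixrec:::project_volume_cpp(unclass(vol), 123.4, 0)
  seg <- helixrec:::rotate_shift_image_cpp(proj, 0, 2, -3)
  mk <- function(m) segment_set(array(m, c(48, 48, 1)),
                                data.frame(filament_id = 1, index = 1), 4,
                                preprocessed = TRUE)
  rec <- align_segments(mk(seg), refs, shift_limit_px = 4, psis = c(0, 180))
  expect_lte(abs(rec$azimuth_deg - 123.4), 2)     # within one azimuth step
  expect_equal(rec$x_shift_px, 2)
  expect_equal(rec$y_shift_px, -3)
  expect_gt(rec$cc, 0.9)   # azimuth is 0.6 deg off the nearest view
  # normalised correlation: invariant to affine intensity changes
  rec2 <- align_segments(mk(5 * seg + 3), refs, shift_limit_px = 4,
                         psis = c(0, 180))
  expect_equal(rec2[c("azimuth_deg", "x_shift_px", "y_shift_px")],
               rec[c("azimuth_deg", "x_shift_px", "y_shift_px")])
  expect_equal(rec2$cc, rec$cc, tolerance = 1e-8)
})

test_that("alignment equals an independent brute-force search", {
  vol <- tiny_volume(n = 32)
  segs <- simulate_segments(vol, 2, 3, noise_sigma = 0.5, tilt_limit_deg = 0,
                            inplane_limit_deg = 0, shift_limit_px = 1,
                            seed = 13)
  pre <- preprocess_segments(segs)
  refs <- make_reference_projections(vol, 30, 0, 1)
  L <- 2
  rec <- align_segments(pre, refs, shift_limit_px = L, psis = c(0, 180))
  n <- 32
  std <- function(m) (m - mean(m)) / sqrt(mean((m - mean(m))^2))
  rot180 <- function(m) m[n:1, n:1]
  cyc <- function(m, sx, sy) m[((0:(n - 1) + sx) %% n) + 1,
                               ((0:(n - 1) + sy) %% n) + 1]
  for (i in seq_len(length(pre))) {
    best <- c(cc = -2, azi = NA, psi = NA, sx = NA, sy = NA)
    for (p in c(0, 180)) {
      a <- pre$images[, , i]
      if (p == 180) a <- rot180(a)
      a <- std(a)
      for (r in seq_len(nrow(refs$labels))) {
        b <- std(refs$images[, , r])
        for (sx in -L:L) for (sy in -L:L) {
          cc <- sum(cyc(a, sx, sy) * b) / n^2
          if (cc > best["cc"] + 1e-9) {
            best <- c(cc = cc, azi = refs$labels$azimuth_deg[r], psi = p,
                      sx = sx, sy = sy)
          }
        }
      }
    }
    expect_equal(unname(best["cc"]), rec$cc[i], tolerance = 1e-8)
    expect_equal(unname(best["azi"]), rec$azimuth_deg[i])
    expect_equal(unname(best["psi"]), rec$in_plane_deg[i])
    expect_equal(unname(best["sx"]), rec$x_shift_px[i])
    expect_equal(unname(best["sy"]), rec$y_shift_px[i])
  }
})

test_that("cc filtering keeps order statistics and guards the pipeline", {
  rec <- data.frame(filament_id = 1, index = 1:10, cc = (1:10) / 10,
                    kept = TRUE, polarity = 1L)
  expect_equal(sum(expect_quiet(filter_by_cc(rec, "percentile", 0))$kept), 10)
  expect_equal(sum(expect_quiet(filter_by_cc(rec, "percentile", 30))$kept), 7)
  expect_equal(sum(expect_quiet(filter_by_cc(rec, "absolute", 1.1))$kept), 0)
  expect_error(filter_by_cc(rec, "percentile", 101), "percentile")
  expect_error(filter_by_cc(rec[0, ], "percentile", 10), "records")
  # never increases the kept count
  set.seed(2)
  for (i in 1:5) {
    r <- data.frame(filament_id = 1, index = 1:20, cc = runif(20),
                    kept = runif(20) > 0.3, polarity = 1L)
    out <- expect_quiet(filter_by_cc(r, "percentile", runif(1, 0, 100)))
    expect_lte(sum(out$kept), sum(r$kept))
  }
})

test_that("filament polarity is resolved by majority vote", {
  rec <- data.frame(filament_id = rep(1:2, c(10, 10)), index = rep(1:10, 2),
                    cc = 1, kept = TRUE,
                    polarity = c(rep(1L, 7), rep(-1L, 3),   # 7 up / 3 down
                                 rep(1L, 5), rep(-1L, 5)))  # exact tie
  out <- expect_quiet(resolve_polarity(rec))
  expect_equal(sum(out$kept[out$filament_id == 1]), 7)
  expect_true(all(out$polarity[out$filament_id == 1 & out$kept] == 1))
  expect_false(any(out$kept[out$filament_id == 2]))

  # 10% per-segment misassignment: the vote recovers >= 99% of filaments
  set.seed(31)
  nfil <- 100; nseg <- 9
  truth <- sample(c(1L, -1L), nfil, replace = TRUE)
  rec2 <- data.frame(
    filament_id = rep(seq_len(nfil), each = nseg),
    index = rep(seq_len(nseg), nfil), cc = 1, kept = TRUE,
    polarity = ifelse(runif(nfil * nseg) < 0.1, -1L, 1L) *
      rep(truth, each = nseg))
  out2 <- expect_quiet(resolve_polarity(rec2))
  maj <- vapply(seq_len(nfil), function(f) {
    k <- out2$kept & out2$filament_id == f
    if (!any(k)) NA_integer_ else out2$polarity[k][1]
  }, 1L)
  expect_gte(mean(maj == truth, na.rm = TRUE), 0.99)
})
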