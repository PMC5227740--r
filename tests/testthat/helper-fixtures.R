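# Shared fixtures: small, quick-to-build objects used across tests.

actomyosin_sym <- function() helical_symmetry(-166.67, 27.6)

# 3-blob chiral asymmetric unit that fits a 48-64 px box at 4 A/px
tiny_asym <- function() {
  pseudo_atom_model(data.frame(
    x = c(10, 40, 62), y = c(0, 14, -10), z = c(0, 6, 12),
    weight = c(3, 2, 1.5), width_A = c(10, 12, 10)), radius_A = 80)
}

tiny_volume <- function(sym = actomyosin_sym(), n = 48, px = 4) {
  build_filament_volume(tiny_asym(), sym, NULL, box_px = n, pixel_A = px)
}

# truth-based alignment records for a simulated segment set
truth_records <- function(segs) {
  m <- segs$meta
  data.frame(filament_id = m$filament_id, index = m$index,
             in_plane_deg = (m$true_inplane_deg +
                               ifelse(m$true_polarity < 0, 180, 0)) %% 360,
             x_shift_px = m$true_dx_px, y_shift_px = m$true_dy_px,
             azimuth_deg = m$true_azimuth_deg, tilt_deg = m$true_tilt_deg,
             cc = 1, kept = TRUE, polarity = m$true_polarity)
}

# independent R trilinear resampling under the helical operator,
# mirroring the documented convention (oracle for the C++ kernel)
r_resample <- function(vol, twist_deg, rise_px) {
  d <- dim(vol)
  ctr <- (d - 1) / 2
  g <- expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1))
  a <- twist_deg * pi / 180
  X <- g$i - ctr[1]; Y <- g$j - ctr[2]
  xs <- cos(a) * X + sin(a) * Y + ctr[1]
  ys <- -sin(a) * X + cos(a) * Y + ctr[2]
  zs <- g$k - rise_px
  ok <- xs >= 0 & ys >= 0 & zs >= 0 &
    xs <= d[1] - 1 & ys <= d[2] - 1 & zs <= d[3] - 1
  val <- rep(NA_real_, nrow(g))
  x0 <- pmax(0, pmin(floor(xs), d[1] - 2))
  y0 <- pmax(0, pmin(floor(ys), d[2] - 2))
  z0 <- pmax(0, pmin(floor(zs), d[3] - 2))
  fx <- xs - x0; fy <- ys - y0; fz <- zs - z0
  at <- function(ii, jj, kk) vol[cbind(ii + 1, jj + 1, kk + 1)]
  idx <- which(ok)
  v <- (at(x0, y0, z0) * (1 - fx) + at(x0 + 1, y0, z0) * fx) *
         (1 - fy) * (1 - fz) +
       (at(x0, y0 + 1, z0) * (1 - fx) + at(x0 + 1, y0 + 1, z0) * fx) *
         fy * (1 - fz) +
       (at(x0, y0, z0 + 1) * (1 - fx) + at(x0 + 1, y0, z0 + 1) * fx) *
         (1 - fy) * fz +
       (at(x0, y0 + 1, z0 + 1) * (1 - fx) +
          at(x0 + 1, y0 + 1, z0 + 1) * fx) * fy * fz
  val[idx] <- v[idx]
  array(val, dim = d)
}

# independent masked mean-squared symmetry residual (oracle)
r_sym_residual <- function(vol, twist_deg, rise_A, mask) {
  rs <- r_resample(unclass(vol), twist_deg, rise_A / pixel_size(vol))
  ok <- !is.na(rs) & mask
  mean((unclass(vol)[ok] - rs[ok])^2)
}

expect_quiet <- function(expr) suppressMessages(suppressWarnings(expr))
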