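#' Split alignment records into filament-respecting halves
#'
#' All segments of a filament land in the same half; halves are
#' balanced by kept-segment count as closely as filament granularity
#' allows, by greedy largest-first assignment (deterministic given the
#' record order; ties go to the first half).
#'
#' @param records alignment records (only `kept` rows count towards
#'   the balance, but whole filaments are assigned).
#' @return list of two record sets `a` and `b`, each with `kept`
#'   restricted to its half.
#' @export
split_halves_by_filament <- function(records) {
  sizes <- table(records$filament_id[records$kept])
  if (length(sizes) < 2L)
    stop("need at least 2 filaments with kept segments to split")
  ord <- order(-as.integer(sizes), names(sizes))
  in_a <- logical(length(sizes))
  na <- nb <- 0L
  for (i in ord) {
    if (na <= nb) {
      in_a[i] <- TRUE
      na <- na + as.integer(sizes[i])
    } else {
      nb <- nb + as.integer(sizes[i])
    }
  }
  fil_a <- names(sizes)[in_a]
  a <- records
  a$kept <- a$kept & (as.character(records$filament_id) %in% fil_a)
  b <- records
  b$kept <- b$kept & !(as.character(records$filament_id) %in% fil_a)
  list(a = a, b = b)
}

#' Fourier shell correlation between two volumes
#'
#' Per shell, `FSC = Re(sum(F_a * conj(F_b))) /
#' sqrt(sum(|F_a|^2) * sum(|F_b|^2))`.  Shells are `shell_width_px`
#' Fourier voxels wide (default 1).
#'
#' @param vol_a,vol_b `volume_grid`s on identical grids.
#' @param shell_width_px shell width in Fourier voxels.
#' @return an `fsc_curve`: data.frame with shell centre frequencies `s`
#'   (1/Angstrom, strictly increasing up to Nyquist), correlations
#'   `fsc`, and voxel counts `n`.
#' @export
fsc_curve <- function(vol_a, vol_b, shell_width_px = 1) {
  if (!identical(dim(vol_a), dim(vol_b)) ||
      !isTRUE(all.equal(pixel_size(vol_a), pixel_size(vol_b))))
    stop("volumes are on different grids")
  d <- dim(vol_a)
  px <- pixel_size(vol_a)
  fa <- fft(unclass(vol_a))
  fb <- fft(unclass(vol_b))
  # radial shell index in Fourier voxels
  rv <- freq_grid_3d(d, px) * d[1] * px
  nshell <- floor(d[1] / 2 / shell_width_px)
  shell <- floor(rv / shell_width_px) + 1L
  inside <- shell <= nshell & rv > 0
  sh <- shell[inside]
  num <- rowsum(Re(fa[inside] * Conj(fb[inside])), sh)
  da <- rowsum(Mod(fa[inside])^2, sh)
  db <- rowsum(Mod(fb[inside])^2, sh)
  cnt <- tabulate(sh, nbins = nshell)
  denom <- sqrt(da[, 1] * db[, 1])
  fsc <- ifelse(denom > 0, num[, 1] / denom, 0)
  centre <- (as.numeric(rownames(num)) - 0.5) * shell_width_px /
    (d[1] * px)
  structure(data.frame(s = centre, fsc = fsc, n = cnt[cnt > 0]),
            class = c("fsc_curve", "data.frame"))
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells to %.4g 1/A; FSC range [%.3f, %.3f]\n",
              nrow(x), max(x$s), min(x$fsc), max(x$fsc)))
  invisible(x)
}

#' Resolution at an FSC threshold
#'
#' Locates the first crossing of the curve below the threshold by
#' linear interpolation between adjacent shells and returns the
#' corresponding real-space resolution `1/s` in Angstrom.  If the
#' curve never drops below the threshold the Nyquist resolution is
#' returned with attribute `crossed = FALSE`.
#'
#' @param curve an [fsc_curve()].
#' @param threshold FSC threshold (0.5 and 0.143 are conventional).
#' @return resolution in Angstrom (attribute `crossed`).
#' @export
resolution_at <- function(curve, threshold) {
  fsc <- curve$fsc
  s <- curve$s
  if (fsc[1] < threshold)
    stop("curve starts below the threshold")
  below <- which(fsc < threshold)
  if (!length(below)) {
    out <- 1 / max(s)
    attr(out, "crossed") <- FALSE
    return(out)
  }
  i <- below[1]
  f <- (fsc[i - 1] - threshold) / (fsc[i - 1] - fsc[i])
  s_cross <- s[i - 1] + f * (s[i] - s[i - 1])
  out <- 1 / s_cross
  attr(out, "crossed") <- TRUE
  out
}

#' Write an FSC curve as two-column tab-separated text
#' @param curve an [fsc_curve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fsc <- function(curve, path) {
  write.table(data.frame(s_invA = curve$s, fsc = curve$fsc), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
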