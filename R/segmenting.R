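#' Filament trace on a micrograph
#'
#' An ordered polyline (in pixel coordinates, 1-based, `x` = row,
#' `y` = column) marking a filament axis, as produced by manual boxing.
#'
#' @param x,y numeric vectors of equal length (>= 2 points).
#' @param micrograph_id identifier string.
#' @param filament_id integer filament identifier.
#' @return object of class `filament_trace`.
#' @export
filament_trace <- function(x, y, micrograph_id = "mic", filament_id = 1L) {
  if (length(x) < 2L || length(x) != length(y))
    stop("a trace needs >= 2 (x, y) points")
  if (any(diff(x) == 0 & diff(y) == 0))
    stop("consecutive trace points must be distinct")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 micrograph_id = micrograph_id,
                 filament_id = as.integer(filament_id)),
            class = "filament_trace")
}

trace_arc_length <- function(trace) {
  sum(sqrt(diff(trace$x)^2 + diff(trace$y)^2))
}

# point at arc-length position t along the polyline
trace_point_at <- function(trace, t) {
  seg_len <- sqrt(diff(trace$x)^2 + diff(trace$y)^2)
  cum <- c(0, cumsum(seg_len))
  t <- min(max(t, 0), cum[length(cum)])
  i <- findInterval(t, cum, rightmost.closed = TRUE)
  f <- (t - cum[i]) / seg_len[i]
  c(trace$x[i] + f * (trace$x[i + 1] - trace$x[i]),
    trace$y[i] + f * (trace$y[i + 1] - trace$y[i]))
}

#' Boxing geometry for filament segments
#'
#' @param box_px box side length, pixels.
#' @param step_px shift between consecutive boxes along the filament
#'   axis (0 < step <= box).
#' @param crop_px post-filter crop side (<= box).
#' @return object of class `box_spec`.
#' @export
box_spec <- function(box_px = 512, step_px = 100, crop_px = 400) {
  if (step_px <= 0 || step_px > box_px)
    stop("need 0 < step_px <= box_px")
  if (crop_px > box_px) stop("crop_px must be <= box_px")
  structure(list(box_px = as.integer(box_px),
                 step_px = as.integer(step_px),
                 crop_px = as.integer(crop_px)), class = "box_spec")
}

#' Number of segments a trace yields under a boxing spec
#'
#' `floor((arc_length - box_px) / step_px) + 1` when the arc length is
#' at least one box, else 0.
#'
#' @param arc_length_px trace arc length, pixels.
#' @param spec a [box_spec()].
#' @return integer count.
#' @export
segment_count <- function(arc_length_px, spec) {
  if (arc_length_px < spec$box_px) return(0L)
  as.integer(floor((arc_length_px - spec$box_px) / spec$step_px) + 1L)
}

#' Box overlapping segments along a filament trace
#'
#' Segment centres are placed every `step_px` along the arc length of
#' the trace, the first centred half a box from the trace start.  Box
#' axes stay image-aligned (no pre-rotation); the full in-plane
#' rotation is left to alignment.  Boxes that would leave the
#' micrograph are skipped with a warning, never silently truncated.
#'
#' @param micrograph numeric matrix.
#' @param trace a [filament_trace()].
#' @param spec a [box_spec()].
#' @param pixel_A pixel size, Angstrom.
#' @return a `segment_set` (possibly with zero segments).
#' @export
box_segments <- function(micrograph, trace, spec, pixel_A = 1.35) {
  stopifnot(inherits(trace, "filament_trace"), inherits(spec, "box_spec"))
  L <- trace_arc_length(trace)
  m <- segment_count(L, spec)
  b <- spec$box_px
  half_lo <- floor(b / 2) - 1L       # centre index offset, 1-based grids
  imgs <- list()
  meta <- list()
  kept <- 0L
  for (i in seq_len(m)) {
    t <- b / 2 + (i - 1) * spec$step_px
    ctr <- round(trace_point_at(trace, t))
    r0 <- ctr[1] - half_lo
    c0 <- ctr[2] - half_lo
    if (r0 < 1 || c0 < 1 || r0 + b - 1L > nrow(micrograph) ||
        c0 + b - 1L > ncol(micrograph)) {
      warning(sprintf(
        "segment %d of filament %d falls outside the micrograph; skipped",
        i, trace$filament_id))
      next
    }
    kept <- kept + 1L
    imgs[[kept]] <- micrograph[r0:(r0 + b - 1L), c0:(c0 + b - 1L)]
    meta[[kept]] <- data.frame(filament_id = trace$filament_id, index = i,
                               micrograph_id = trace$micrograph_id,
                               centre_x = ctr[1], centre_y = ctr[2])
  }
  images <- array(0, dim = c(b, b, kept))
  for (i in seq_len(kept)) images[, , i] <- imgs[[i]]
  segment_set(images,
              if (kept) do.call(rbind, meta)
              else data.frame(filament_id = integer(), index = integer()),
              pixel_A = pixel_A)
}

#' Per-segment preprocessing: CTF, high-pass, normalise, crop
#'
#' The order of operations is: multiply by the segment's CTF (so the
#' structure factor carries CTF^2 and noise at CTF nodes is
#' suppressed), high-pass filter to remove slow background undulation,
#' normalise to zero mean and unit variance over the whole box, and
#' centre-crop.  The applied CTF is recorded in a shell accumulator for
#' the final `1/[sum(CTF^2) + 1/SNR]` restoration.
#'
#' @param segment square numeric matrix.
#' @param ctf a [ctf_params()].
#' @param high_pass_A high-pass cutoff, Angstrom (default 285).
#' @param crop_px output side length (default: no crop).
#' @return processed matrix.
#' @export
preprocess_segment <- function(segment, ctf, high_pass_A = 285,
                               crop_px = NULL) {
  if (nrow(segment) != ncol(segment)) stop("segment must be square")
  n <- nrow(segment)
  if (var(as.numeric(segment)) == 0)
    stop("zero-variance segment rejected")
  out <- apply_ctf(segment, ctf)
  if (!is.null(high_pass_A))
    out <- bandpass(out, high_pass_A = high_pass_A, pixel_A = ctf$pixel_A)
  out <- (out - mean(out)) / sd(as.numeric(out))
  if (!is.null(crop_px) && crop_px < n) {
    i0 <- floor((n - crop_px) / 2) + 1L
    out <- out[i0:(i0 + crop_px - 1L), i0:(i0 + crop_px - 1L)]
  }
  out
}

#' Preprocess every segment of a set
#'
#' Applies [preprocess_segment()] to each image with its own CTF and
#' attaches the CTF^2 shell accumulator to the returned set.
#'
#' @param segs a `segment_set`.
#' @inheritParams preprocess_segment
#' @return a preprocessed `segment_set` with a `ctf2_acc` element.
#' @export
preprocess_segments <- function(segs, high_pass_A = 285, crop_px = NULL) {
  stopifnot(inherits(segs, "segment_set"))
  if (isTRUE(segs$preprocessed)) stop("segments already preprocessed")
  n_in <- dim(segs$images)[1]
  n_out <- if (is.null(crop_px)) n_in else as.integer(crop_px)
  S <- length(segs)
  images <- array(0, dim = c(n_out, n_out, S))
  acc <- ctf2_accumulator(n_out, segs$pixel_A)
  for (i in seq_len(S)) {
    ctf <- segment_ctf(segs, i)
    images[, , i] <- preprocess_segment(segs$images[, , i], ctf,
                                        high_pass_A = high_pass_A,
                                        crop_px = crop_px)
    acc <- accumulate_ctf2(acc, ctf_evaluate(ctf, n_out))
  }
  out <- segment_set(images, segs$meta, pixel_A = segs$pixel_A,
                     voltage_kV = segs$voltage_kV, cs_mm = segs$cs_mm,
                     amp_contrast = segs$amp_contrast,
                     preprocessed = TRUE)
  out$ctf2_acc <- acc
  out
}

#' Average CTF (or CTF power) of a segment set at a given image size
#'
#' Used to CTF-match reference projections to preprocessed segments.
#' Preprocessed segments carry CTF^2 on their structure factor (the
#' microscope contributes one CTF, the correction multiplies a
#' second), so matched references use `power = 2`.
#'
#' @param segs a `segment_set`.
#' @param n image side, pixels.
#' @param power 1 for the mean CTF, 2 for the mean squared CTF.
#' @return n x n matrix (mean of the per-segment CTF powers).
#' @export
average_ctf <- function(segs, n, power = 1) {
  S <- length(segs)
  acc <- matrix(0, n, n)
  for (i in seq_len(S))
    acc <- acc + ctf_evaluate(segment_ctf(segs, i), n)^power
  acc / S
}

#' Read / write filament traces as tab-separated text
#'
#' One row per point (`micrograph_id`, `filament_id`, `x`, `y`).
#'
#' @param traces list of [filament_trace()] objects.
#' @param path file path.
#' @return for `read_traces`, a list of `filament_trace`s.
#' @export
write_traces <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr)
    data.frame(micrograph_id = tr$micrograph_id,
               filament_id = tr$filament_id, x = tr$x, y = tr$y)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE)
  lapply(split(d, d$filament_id), function(g)
    filament_trace(g$x, g$y, micrograph_id = g$micrograph_id[1],
                   filament_id = g$filament_id[1]))
}
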