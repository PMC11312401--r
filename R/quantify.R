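#' Extract the crossing-position trace along a scan line
#'
#' The line-scan (kymograph) reduction at the heart of the measurement: for
#' every frame, intensity is sampled along the scan line by bilinear
#' interpolation, the static background is removed by subtracting the
#' spatial median of the profile, and the crossing position of the filament
#' is estimated from the dominant peak: an intensity-weighted centroid of
#' the contiguous region above half the peak height, refined to sub-sample
#' precision by a Gaussian fit (parabola on log intensity) over the peak
#' top. Positions are reported in um from endpoint `a`. The per-frame
#' `quality` in [0, 1] is the peak contrast relative to the residual
#' profile noise.
#'
#' @param stack a `frame_stack`.
#' @param line a [scan_line]; by default derived from the stack's attached
#'   geometry.
#' @return A `position_trace`: data frame with columns `time_ms`,
#'   `position_um`, `quality`, plus the line and frame rate as attributes.
#' @export
extract_trace <- function(stack, line = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(line)) {
    if (is.null(stack$geometry))
      stop("no scan line given and the stack carries no geometry",
           call. = FALSE)
    line <- default_scan_line(stack$geometry)
  }
  d <- dim(stack$frames)
  w <- d[1]; h <- d[2]; n <- d[3]
  px <- stack$config$pixel_size
  ns <- line$n_samples
  tt <- seq(0, 1, length.out = ns)
  sx <- line$a[1] + tt * (line$b[1] - line$a[1])
  sy <- line$a[2] + tt * (line$b[2] - line$a[2])
  dist_um <- tt * line$length

  fx <- sx / px + 0.5
  fy <- sy / px + 0.5
  if (any(fx < 1 | fx > w | fy < 1 | fy > h))
    stop("scan line extends outside the frame", call. = FALSE)
  i0 <- pmin(floor(fx), w - 1); j0 <- pmin(floor(fy), h - 1)
  ax <- fx - i0; ay <- fy - j0
  i00 <- i0 + (j0 - 1) * w; i10 <- i00 + 1
  i01 <- i0 + j0 * w;       i11 <- i01 + 1
  w00 <- (1 - ax) * (1 - ay); w10 <- ax * (1 - ay)
  w01 <- (1 - ax) * ay;       w11 <- ax * ay

  pos <- numeric(n); qual <- numeric(n); contrast <- numeric(n)
  for (k in seq_len(n)) {
    fr <- stack$frames[, , k]
    prof <- fr[i00] * w00 + fr[i10] * w10 + fr[i01] * w01 + fr[i11] * w11
    prof <- prof - stats::median(prof)
    pk <- which.max(prof)
    height <- prof[pk]
    half <- height / 2
    lo <- pk; while (lo > 1 && prof[lo - 1] >= half) lo <- lo - 1
    hi <- pk; while (hi < ns && prof[hi + 1] >= half) hi <- hi + 1
    region <- lo:hi
    wts <- prof[region]
    cen <- if (sum(wts) > 0) sum(dist_um[region] * wts) / sum(wts)
           else dist_um[pk]
    pos[k] <- gaussian_peak_refine(prof, dist_um, pk, height, fallback = cen)
    resid <- prof[-region]
    noise <- stats::mad(resid, center = 0)
    contrast[k] <- height
    qual[k] <- if (height <= 0) 0 else height / (height + 5 * noise + 1e-9)
  }

  ## a line that never crosses the filament gives a flat profile every frame
  noise_floor <- stats::mad(stack$frames, center = stats::median(stack$frames))
  if (all(contrast <= 5 * noise_floor + 1e-6))
    stop("no crossing detected: scan line does not intersect the beat ",
         "envelope in any frame", call. = FALSE)

  out <- data.frame(time_ms = (seq_len(n) - 1) * 1000 / stack$config$fps,
                    position_um = pos, quality = qual)
  attr(out, "line") <- line
  attr(out, "fps") <- stack$config$fps
  class(out) <- c("position_trace", "data.frame")
  out
}

## Sub-sample refinement of the profile peak: the PSF-blurred filament
## cross-section is close to Gaussian, so a parabola fitted to the log
## intensity of the peak top gives the crossing position with ~1/10 sample
## precision. Falls back to the centroid when the fit is degenerate.
gaussian_peak_refine <- function(prof, dist_um, pk, height, fallback) {
  if (!is.finite(height) || height <= 0) return(fallback)
  keep <- which(prof >= 0.3 * height & prof > 0)
  keep <- keep[abs(keep - pk) <= 12]
  if (length(keep) < 5) return(fallback)
  d <- dist_um[keep]
  z <- log(prof[keep])
  ## closed-form quadratic least squares z ~ a + b d + c d^2
  d0 <- d - d[1]
  X <- cbind(1, d0, d0^2)
  b <- tryCatch(solve(crossprod(X), crossprod(X, z)),
                error = function(e) NULL)
  if (is.null(b) || b[3] >= 0) return(fallback)
  est <- d[1] - b[2] / (2 * b[3])
  if (est < min(d) || est > max(d)) return(fallback)
  est
}

#' Suggest a scan line from the temporal-variance map
#'
#' Computes the per-pixel temporal variance of the stack — high wherever the
#' filament sweeps — and proposes a line through the maximum-variance point
#' across the swept band: the band is elongated along the filament, so the
#' line runs along its minor principal axis, i.e. across the direction of
#' motion. Placement remains the user's decision; this is only a starting
#' suggestion.
#'
#' @param stack a `frame_stack`.
#' @param half_length half-length of the suggested line, um; by default
#'   2.5 variance-weighted standard deviations across the band plus a 1 um
#'   margin.
#' @return A [scan_line].
#' @export
suggest_scan_line <- function(stack, half_length = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  px <- stack$config$pixel_size
  mu <- rowMeans(stack$frames, dims = 2)
  v <- rowMeans(stack$frames^2, dims = 2) - mu^2
  w <- pmax(v - stats::median(v), 0)
  if (sum(w) <= 0)
    stop("no temporal variance: nothing moves in this stack", call. = FALSE)
  xs <- (seq_len(d[1]) - 0.5) * px
  ys <- (seq_len(d[2]) - 0.5) * px
  wx <- rowSums(w); wy <- colSums(w)
  cx <- sum(xs * wx) / sum(wx); cy <- sum(ys * wy) / sum(wy)
  ## variance-weighted second moments -> principal axis of the swept region
  gx <- matrix(xs - cx, d[1], d[2])
  gy <- matrix(ys - cy, d[1], d[2], byrow = TRUE)
  cov <- matrix(c(sum(w * gx * gx), sum(w * gx * gy),
                  sum(w * gx * gy), sum(w * gy * gy)), 2, 2) / sum(w)
  eg <- eigen(cov, symmetric = TRUE)
  axis <- eg$vectors[, 2]                      # across the swept band
  if (is.null(half_length))
    half_length <- 2.5 * sqrt(max(eg$values[2], 0)) + 1
  top <- arrayInd(which.max(w), d[1:2])
  p0 <- c((top[1] - 0.5) * px, (top[2] - 0.5) * px)
  ## clip to the frame with a half-pixel margin
  lim <- c(d[1], d[2]) * px
  for (s in c(-1, 1)) {
    endp <- p0 + s * half_length * axis
    over <- pmax((endp - (lim - px)) / (abs(axis) + 1e-12),
                 ((0 + px) - endp) / (abs(axis) + 1e-12), 0)
    half_length <- half_length - max(pmin(over, half_length))
  }
  scan_line(a = p0 - half_length * axis, b = p0 + half_length * axis,
            rest_offset = NA_real_)
}

#' Build a position trace directly from numeric vectors
#'
#' Used for trace-level analyses (e.g. detection statistics on pure
#' fluctuation traces) and for testing the detector independently of the
#' renderer.
#'
#' @param time_ms sample times, ms.
#' @param position_um positions, um.
#' @param quality optional per-sample confidence in [0, 1].
#' @param fps frames per second (inferred from the time grid if omitted).
#' @return A `position_trace`.
#' @export
as_position_trace <- function(time_ms, position_um, quality = 1,
                              fps = NULL) {
  stopifnot(length(time_ms) == length(position_um))
  if (is.null(fps)) fps <- 1000 / diff(time_ms[1:2])
  out <- data.frame(time_ms = time_ms, position_um = position_um,
                    quality = rep_len(quality, length(time_ms)))
  attr(out, "fps") <- fps
  class(out) <- c("position_trace", "data.frame")
  out
}

#' @export
plot.position_trace <- function(x, ...) {
  graphics::plot(x$time_ms, x$position_um, type = "l",
                 xlab = "time (ms)", ylab = "position (um)", ...)
  invisible(x)
}

## Topographic prominence of local maxima: for each candidate peak, walk out
## to the nearest strictly higher sample on each side (or the record edge);
## the prominence is the peak height minus the higher of the two valley
## minima found on the way.
##
## Edge rule: a beat whose rise (or fall) is cut off by the record edge
## still counts as a peak, so a side whose valley floor sits exactly on the
## record edge, with a near-monotone ramp from the edge to the peak close
## by, does not constrain the prominence.
peak_prominence <- function(x, peaks, edge_window = 60L, step_tol = 0.02) {
  n <- length(x)
  clipped_side <- function(seg) {
    length(seg) <= edge_window &&
      which.min(seg) == 1L &&
      all(diff(seg) >= -step_tol)
  }
  vapply(peaks, function(p) {
    hp <- x[p]
    lmin <- hp; i <- p
    while (i > 1 && x[i - 1] <= hp) { i <- i - 1; lmin <- min(lmin, x[i]) }
    lbase <- if (i == 1 && x[i] <= hp) min(lmin, x[1]) else lmin
    l_clip <- i == 1 && x[i] <= hp && clipped_side(x[1:p])
    rmin <- hp; i <- p
    while (i < n && x[i + 1] <= hp) { i <- i + 1; rmin <- min(rmin, x[i]) }
    rbase <- if (i == n && x[i] <= hp) min(rmin, x[n]) else rmin
    r_clip <- i == n && x[i] <= hp && clipped_side(rev(x[p:n]))
    if (l_clip && r_clip) hp - min(lbase, rbase)
    else if (l_clip) hp - rbase
    else if (r_clip) hp - lbase
    else hp - max(lbase, rbase)
  }, numeric(1))
}

## Local maxima, robust to flat-topped peaks (plateaus count once, at their
## center).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  dx <- diff(x)
  keep <- dx[dx != 0]
  if (!length(keep)) return(integer(0))
  ## collapse zero-runs: index of last sample before each nonzero diff
  nz <- which(dx != 0)
  sign_seq <- sign(dx[nz])
  peaks <- integer(0)
  for (i in seq_len(length(nz) - 1)) {
    if (sign_seq[i] > 0 && sign_seq[i + 1] < 0) {
      lo <- nz[i] + 1       # first sample of the plateau/top
      hi <- nz[i + 1]       # last sample of the plateau/top
      peaks <- c(peaks, floor((lo + hi) / 2))
    }
  }
  peaks
}

#' Detect beats as prominent maxima of the position trace
#'
#' Local maxima with topographic prominence at least `min_prominence` and
#' pairwise separation at least `min_separation` (closer peaks lose to the
#' more prominent one). Each kept peak is matched to its preceding trough
#' (the last minimum between the previous peak, or the record start, and the
#' peak); a trough falling on the very first sample of the record is flagged
#' incomplete and its wave is excluded from bend-distance averaging.
#'
#' The default prominence of 0.2 um sits below the smallest stimulated bend
#' distance (0.57 um) and above the non-beating fluctuation scale; the
#' default separation of 20 ms (5 frames) is below the shortest plausible
#' cycle (~65 ms at 15.4 Hz).
#'
#' @param trace a `position_trace`.
#' @param min_prominence minimum topographic prominence, um (> 0).
#' @param min_separation minimum peak separation, ms.
#' @return A `beat_peaks` list: `peaks`, `troughs` (sample indices),
#'   `trough_complete` (logical), `prominence`, `peak_times` (ms). An empty
#'   result is valid.
#' @export
detect_beats <- function(trace, min_prominence = 0.2, min_separation = 20) {
  stopifnot(inherits(trace, "position_trace"), min_prominence > 0)
  x <- trace$position_um
  cand <- local_maxima(x)
  res <- list(peaks = integer(0), troughs = integer(0),
              trough_complete = logical(0), prominence = numeric(0),
              peak_times = numeric(0))
  class(res) <- "beat_peaks"
  if (!length(cand)) return(res)
  prom <- peak_prominence(x, cand)
  ok <- prom >= min_prominence
  cand <- cand[ok]; prom <- prom[ok]
  if (!length(cand)) return(res)

  fps <- attr(trace, "fps")
  min_sep_samples <- min_separation / (1000 / fps)
  ord <- order(-prom)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(cand[i] - cand[kept]) >= min_sep_samples))
      kept <- c(kept, i)
  }
  kept <- kept[order(cand[kept])]
  peaks <- cand[kept]; prom <- prom[kept]

  troughs <- integer(length(peaks))
  complete <- logical(length(peaks))
  for (i in seq_along(peaks)) {
    seg_start <- if (i == 1) 1L else peaks[i - 1]
    seg <- seg_start:peaks[i]
    mins <- which(x[seg] == min(x[seg]))
    troughs[i] <- seg[mins[length(mins)]]       # last tie: adjacent to the rise
    complete[i] <- !(i == 1 && troughs[i] == 1L && length(mins) == 1L)
  }
  res$peaks <- peaks; res$troughs <- troughs
  res$trough_complete <- complete; res$prominence <- prom
  res$peak_times <- trace$time_ms[peaks]
  res
}

#' @export
print.beat_peaks <- function(x, ...) {
  cat(sprintf("Detected beats: %d peaks\n", length(x$peaks)))
  invisible(x)
}

#' Ciliary beat frequency from counted peaks
#'
#' The number of detected peaks divided by the record duration.
#'
#' @param beats a `beat_peaks` result (or an integer vector of peak
#'   indices).
#' @param record_duration_s record duration in seconds (> 0).
#' @return CBF in Hz.
#' @export
compute_cbf <- function(beats, record_duration_s) {
  if (!is.numeric(record_duration_s) || record_duration_s <= 0)
    stop("record_duration_s must be > 0", call. = FALSE)
  n <- if (inherits(beats, "beat_peaks")) length(beats$peaks)
       else length(beats)
  n / record_duration_s
}

#' Ciliary bend distance from peak-to-trough excursions
#'
#' The mean peak-minus-preceding-trough distance over the first
#' `min(n_waves, available)` complete waves (a wave whose preceding trough
#' is cut off by the record edge is excluded).
#'
#' @param trace a `position_trace`.
#' @param beats a `beat_peaks` result from [detect_beats()].
#' @param n_waves number of waves to average over (default 10).
#' @return A list with `cbd` (um; `NA` if no complete wave — undefined,
#'   which is distinct from 0) and `n_waves_used`.
#' @export
compute_cbd <- function(trace, beats, n_waves = 10) {
  stopifnot(inherits(beats, "beat_peaks"))
  ok <- which(beats$trough_complete)
  if (!length(ok)) return(list(cbd = NA_real_, n_waves_used = 0L))
  use <- ok[seq_len(min(n_waves, length(ok)))]
  x <- trace$position_um
  d <- x[beats$peaks[use]] - x[beats$troughs[use]]
  list(cbd = mean(d), n_waves_used = length(use))
}

#' Full single-recording quantification
#'
#' Runs [extract_trace()], [detect_beats()], [compute_cbf()] and
#' [compute_cbd()] on one frame stack, mirroring the standard 2 s
#' measurement protocol.
#'
#' @param stack a `frame_stack`.
#' @param line optional [scan_line].
#' @param min_prominence,min_separation detector settings, see
#'   [detect_beats()].
#' @param n_waves waves averaged for the bend distance.
#' @return A `beat_measurement`: list with `cbf` (Hz), `cbd` (um),
#'   `peak_times` (ms), `trough_depths` (um), `n_waves_used`, and the trace
#'   and detection attached.
#' @export
quantify_stack <- function(stack, line = NULL, min_prominence = 0.2,
                           min_separation = 20, n_waves = 10) {
  trace <- extract_trace(stack, line)
  quantify_trace(trace, min_prominence, min_separation, n_waves)
}

#' @rdname quantify_stack
#' @param trace a `position_trace` (trace-level entry point).
#' @export
quantify_trace <- function(trace, min_prominence = 0.2,
                           min_separation = 20, n_waves = 10) {
  beats <- detect_beats(trace, min_prominence, min_separation)
  dur <- length(trace$position_um) / attr(trace, "fps")
  cbf <- compute_cbf(beats, dur)
  cbd <- compute_cbd(trace, beats, n_waves)
  structure(list(cbf = cbf, cbd = cbd$cbd,
                 n_waves_used = cbd$n_waves_used,
                 peak_times = beats$peak_times,
                 trough_depths = trace$position_um[beats$troughs],
                 record_duration_s = dur,
                 trace = trace, beats = beats),
            class = "beat_measurement")
}

#' @export
print.beat_measurement <- function(x, ...) {
  cat(sprintf("Beat measurement over %.3g s:\n", x$record_duration_s))
  cat(sprintf("  CBF: %.3g Hz (%d peaks)\n", x$cbf, length(x$peak_times)))
  if (is.na(x$cbd)) cat("  CBD: undefined (no complete wave)\n")
  else cat(sprintf("  CBD: %.3g um over %d waves\n", x$cbd, x$n_waves_used))
  invisible(x)
}

#' Export a trace or measurement to CSV
#'
#' @param trace a `position_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param measurement a `beat_measurement`.
#' @export
write_measurement <- function(measurement, path) {
  utils::write.csv(data.frame(
    cbf_hz = measurement$cbf, cbd_um = measurement$cbd,
    n_waves_used = measurement$n_waves_used,
    peak_times = paste(measurement$peak_times, collapse = ";")),
    path, row.names = FALSE)
  invisible(path)
}
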