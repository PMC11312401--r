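#' Render a beat trajectory into a synthetic grayscale frame stack
#'
#' Each frame is the sum of a constant background and the filament image:
#' the posed centerline ([pose_cilium()]) is integrated onto the pixel grid
#' (bilinear splatting of dense arc samples, conserving total brightness),
#' convolved with a Gaussian point-spread function, and optionally corrupted
#' with Poisson shot noise and additive Gaussian read noise. Pixel values
#' are quantized to 16-bit integers. With noise off the output is
#' deterministic given its inputs.
#'
#' The renderer refuses configurations sampled at fewer than 6 frames per
#' beat cycle (the beat would be temporally aliased).
#'
#' @param trajectory a `beat_trajectory` (its 4 ms grid must match
#'   `config$fps`).
#' @param geometry a [cilium_geometry].
#' @param config an [imaging_config].
#' @param seed optional integer seed for the noise stream.
#' @return A `frame_stack`: list with `frames` (array `width x height x
#'   n_frames`), `config`, `geometry`, and the generating trajectory in
#'   `truth`.
#' @examples
#' p <- beat_params(44, 38, 120, interval_sigma_log = 0, amplitude = 0.98,
#'                  mode = "component_matched")
#' tr <- build_trajectory(p, duration_s = 0.4)
#' st <- render_stack(tr, config = imaging_config(noise_sd = 0))
#' dim(st$frames)
#' @export
render_stack <- function(trajectory, geometry = cilium_geometry(),
                         config = imaging_config(), seed = NULL) {
  stopifnot(inherits(trajectory, "beat_trajectory"),
            inherits(geometry, "cilium_geometry"),
            inherits(config, "imaging_config"))
  n <- length(trajectory$times)
  if (n == 0) stop("empty trajectory", call. = FALSE)
  frame_ms <- 1000 / config$fps
  if (n > 1 && abs(diff(trajectory$times[1:2]) - frame_ms) > 1e-9)
    stop("trajectory time grid does not match config fps", call. = FALSE)

  cyc <- trajectory$kinematics$cycle_mean
  if (is.finite(cyc) && cyc / frame_ms < 6)
    stop(sprintf(
      "beat cycle of %.1f ms gives %.1f frames per cycle at %g fps (< 6): refusing aliased render",
      cyc, cyc / frame_ms, config$fps), call. = FALSE)

  w <- config$frame_shape[1]; h <- config$frame_shape[2]
  px <- config$pixel_size
  ds <- px / 5
  n_arc <- max(64L, ceiling(geometry$length / ds))

  ## identical poses (e.g. every rest-phase frame) are rendered once
  key <- signif(trajectory$positions, 12)
  uk <- unique(key)
  slot <- match(key, uk)
  uniq <- array(0, dim = c(w, h, length(uk)))

  for (u in seq_along(uk)) {
    pts <- pose_cilium(geometry, uk[u], n_points = n_arc)
    seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
    wgt <- config$filament_intensity * c(seg / 2, 0) +
           config$filament_intensity * c(0, seg / 2)
    ## fractional pixel indices (pixel i center at (i - 0.5) * px)
    fx <- pts[, 1] / px + 0.5
    fy <- pts[, 2] / px + 0.5
    bad <- fx < 1 | fx > w | fy < 1 | fy > h
    if (any(bad)) {
      k <- which(slot == u)[1]
      stop(sprintf(
        "cilium pose exits the frame at t = %g ms (frame %d, displacement %.3g um)",
        trajectory$times[k], k, trajectory$positions[k]), call. = FALSE)
    }
    i0 <- floor(fx); j0 <- floor(fy)
    ax <- fx - i0; ay <- fy - j0
    i1 <- pmin(i0 + 1, w); j1 <- pmin(j0 + 1, h)
    idx <- c(i0 + (j0 - 1) * w, i1 + (j0 - 1) * w,
             i0 + (j1 - 1) * w, i1 + (j1 - 1) * w)
    val <- c(wgt * (1 - ax) * (1 - ay), wgt * ax * (1 - ay),
             wgt * (1 - ax) * ay, wgt * ax * ay)
    acc <- rowsum(val, group = idx)
    fr <- numeric(w * h)
    fr[as.integer(rownames(acc))] <- acc[, 1]
    uniq[, , u] <- fr
  }

  if (config$psf_sigma > 0)
    uniq <- EBImage::gblur(uniq, sigma = config$psf_sigma / px)
  frames <- uniq[, , slot, drop = FALSE]
  frames <- frames + config$background_level

  with_seed_(seed, {
    if (config$shot_noise)
      frames[] <- stats::rpois(length(frames), lambda = pmax(frames, 0))
    if (config$noise_sd > 0)
      frames <- frames + stats::rnorm(length(frames), 0, config$noise_sd)
  })
  frames <- round(pmin(pmax(frames, 0), 65535))

  structure(list(frames = frames, config = config, geometry = geometry,
                 truth = trajectory),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "Frame stack: %d frames of %d x %d px (%g um/px, %g fps, %.3g s)\n",
    d[3], d[1], d[2], x$config$pixel_size, x$config$fps, d[3] / x$config$fps))
  if (!is.null(x$truth)) cat("  ground-truth trajectory attached\n")
  invisible(x)
}

#' Write / read a frame stack as multi-page TIFF
#'
#' Pixel data are written losslessly as 16-bit grayscale TIFF pages, one per
#' frame. Acquisition metadata (`fps`, `pixel_size`) that the TIFF writer
#' cannot store as tags go to a JSON sidecar (`<path>.json`), read back by
#' [read_stack()].
#'
#' @param stack a `frame_stack`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[3]), function(k)
    t(stack$frames[, , k]) / 65535)   # rows = y for the TIFF writer
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "deflate",
                  reduce = FALSE)
  jsonlite::write_json(
    list(fps = stack$config$fps, pixel_size = stack$config$pixel_size,
         frame_shape = stack$config$frame_shape),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param fps,pixel_size acquisition metadata; required for foreign TIFFs
#'   without a JSON sidecar.
#' @return `read_stack()` returns a `frame_stack` (without ground truth).
#' @export
read_stack <- function(path, fps = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such TIFF file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent page shapes in TIFF: ", path, call. = FALSE)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    if (is.null(fps)) fps <- meta$fps
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size
  }
  if (is.null(fps) || is.null(pixel_size))
    stop("fps and pixel_size must be supplied for a foreign TIFF without ",
         "a metadata sidecar", call. = FALSE)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(0, dim = c(w, h, length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    frames[, , k] <- t(round(pg * 65535))
  }
  cfg <- imaging_config(fps = fps, pixel_size = pixel_size,
                        frame_shape = c(w, h))
  structure(list(frames = frames, config = cfg, geometry = NULL,
                 truth = NULL),
            class = "frame_stack")
}
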