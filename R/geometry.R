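#' Imaging configuration for synthetic recordings
#'
#' Describes the virtual microscope/camera: frame rate, pixel pitch, frame
#' geometry, point-spread-function width and noise. Defaults emulate
#' high-speed video microscopy of a sub-resolution (100 nm) filament:
#' 250 fps, 0.1 um/px, Gaussian PSF sd 0.15 um, so a 0.5-1.5 um beat
#' excursion spans 5-15 px.
#'
#' @param fps frames per second (> 0).
#' @param pixel_size um per pixel (> 0).
#' @param frame_shape integer vector `c(width, height)` in pixels.
#' @param psf_sigma Gaussian blur sd in um (>= 0).
#' @param background_level constant background, grayscale units.
#' @param filament_intensity integrated filament brightness per um of arc,
#'   grayscale units.
#' @param noise_sd additive Gaussian read-noise sd, grayscale units.
#' @param shot_noise logical; apply Poisson shot noise to pixel values.
#' @return An `imaging_config` object.
#' @export
imaging_config <- function(fps = 250, pixel_size = 0.1,
                           frame_shape = c(128L, 128L), psf_sigma = 0.15,
                           background_level = 200, filament_intensity = 4000,
                           noise_sd = 4, shot_noise = FALSE) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(is.numeric(fps) && length(fps) == 1 && fps > 0, "fps must be > 0")
  chk(is.numeric(pixel_size) && pixel_size > 0, "pixel_size must be > 0")
  chk(is.numeric(frame_shape) && length(frame_shape) == 2 &&
        all(frame_shape >= 8), "frame_shape must be two pixel counts >= 8")
  chk(is.numeric(psf_sigma) && psf_sigma >= 0, "psf_sigma must be >= 0")
  chk(is.numeric(background_level) && background_level >= 0,
      "background_level must be >= 0")
  chk(is.numeric(filament_intensity) && filament_intensity > 0,
      "filament_intensity must be > 0")
  chk(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  chk(is.logical(shot_noise), "shot_noise must be TRUE or FALSE")
  if (length(errs))
    stop("invalid imaging config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(list(fps = fps, pixel_size = pixel_size,
                 frame_shape = as.integer(frame_shape),
                 psf_sigma = psf_sigma, background_level = background_level,
                 filament_intensity = filament_intensity,
                 noise_sd = noise_sd, shot_noise = shot_noise),
            class = "imaging_config")
}

#' @export
print.imaging_config <- function(x, ...) {
  cat(sprintf(
    "Imaging config: %d x %d px at %g um/px, %g fps, PSF sd %g um\n",
    x$frame_shape[1], x$frame_shape[2], x$pixel_size, x$fps, x$psf_sigma))
  cat(sprintf("  background %g, filament %g/um, noise sd %g%s\n",
              x$background_level, x$filament_intensity, x$noise_sd,
              if (x$shot_noise) ", shot noise on" else ""))
  invisible(x)
}

#' Geometry of the anchored cilium in the image plane
#'
#' One end of the cilium is attached to the coverslip (the anchor); the
#' unbent filament points along `base_angle`. The scan line crosses the
#' filament at `scanline_fraction` of its length.
#'
#' @param length filament length, um.
#' @param anchor image coordinates of the fixed end, um (`c(x, y)`).
#' @param base_angle orientation of the unbent cilium, degrees.
#' @param scanline_fraction fractional position of the scan-line crossing
#'   along the base pose, in (0, 1].
#' @return A `cilium_geometry` object.
#' @export
cilium_geometry <- function(length = 10, anchor = c(1.5, 6.4),
                            base_angle = 0, scanline_fraction = 0.7) {
  stopifnot(is.numeric(length), length > 0,
            is.numeric(anchor), base::length(anchor) == 2,
            is.numeric(base_angle),
            is.numeric(scanline_fraction),
            scanline_fraction > 0, scanline_fraction <= 1)
  structure(list(length = length, anchor = anchor,
                 base_angle = base_angle,
                 scanline_fraction = scanline_fraction),
            class = "cilium_geometry")
}

#' Pose the cilium centerline for a given scan-line displacement
#'
#' The bent filament is modeled as a circular arc pinned at the anchor and
#' tangent to the base orientation there, with curvature chosen in closed
#' form so that the arc crosses the scan line (the perpendicular through the
#' point at `scanline_fraction` of the base pose) at a lateral offset of
#' exactly `displacement`. Arc length is preserved exactly (the arc is
#' parameterized by arc length), and `displacement = 0` gives the straight
#' base pose. Mirrored displacements give mirror-image centerlines.
#'
#' @param geometry a [cilium_geometry].
#' @param displacement lateral crossing offset on the scan line, um (signed).
#' @param n_points number of centerline points returned.
#' @return An `n_points` x 2 matrix of image coordinates in um, ordered from
#'   anchor to tip.
#' @export
pose_cilium <- function(geometry, displacement, n_points = 200) {
  L <- geometry$length
  x0 <- geometry$scanline_fraction * L
  s <- seq(0, L, length.out = n_points)
  if (abs(displacement) < 1e-12) {
    local <- cbind(s, 0 * s)
  } else {
    cc <- displacement / x0
    if (abs(cc) >= 1)
      stop("displacement too large for the scan-line position", call. = FALSE)
    kappa <- (2 * cc / (1 + cc^2)) / x0
    theta <- kappa * s
    local <- cbind(sin(theta) / kappa, (1 - cos(theta)) / kappa)
  }
  ang <- geometry$base_angle * pi / 180
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  sweep(local %*% t(rot), 2, geometry$anchor, `+`)
}

#' Default scan line through the beat envelope
#'
#' The scan line is perpendicular to the base pose, through the point at
#' `scanline_fraction` of the filament length, extending `below` um on the
#' side opposite the beat and `above` um on the beat side.
#'
#' @param geometry a [cilium_geometry].
#' @param below,above extent of the line on either side of the rest
#'   position, um.
#' @return A [scan_line].
#' @export
default_scan_line <- function(geometry, below = 1, above = 3.5) {
  x0 <- geometry$scanline_fraction * geometry$length
  ang <- geometry$base_angle * pi / 180
  u <- c(cos(ang), sin(ang))        # along base pose
  v <- c(-sin(ang), cos(ang))       # lateral (beat) direction
  p0 <- geometry$anchor + x0 * u
  scan_line(a = p0 - below * v, b = p0 + above * v,
            rest_offset = below)
}

#' A scan line across the beat envelope
#'
#' @param a,b endpoint image coordinates, um (`c(x, y)` each).
#' @param n_samples number of interpolation points along the line; default
#'   one sample per 0.02 um.
#' @param rest_offset distance from `a` to the rest position of the
#'   filament, um, if known (used only for reporting).
#' @return A `scan_line` object with fields `a`, `b`, `length`, `n_samples`.
#' @export
scan_line <- function(a, b, n_samples = NULL, rest_offset = NA_real_) {
  stopifnot(is.numeric(a), length(a) == 2, is.numeric(b), length(b) == 2)
  len <- sqrt(sum((b - a)^2))
  if (len <= 0) stop("scan line endpoints coincide", call. = FALSE)
  if (is.null(n_samples)) n_samples <- max(50L, ceiling(len / 0.02))
  structure(list(a = a, b = b, length = len,
                 n_samples = as.integer(n_samples),
                 rest_offset = rest_offset),
            class = "scan_line")
}

#' @export
print.scan_line <- function(x, ...) {
  cat(sprintf("Scan line (%.2f, %.2f) -> (%.2f, %.2f) um, %.2f um, %d samples\n",
              x$a[1], x$a[2], x$b[1], x$b[2], x$length, x$n_samples))
  invisible(x)
}
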