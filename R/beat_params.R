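#' Kinematic parameters of one beating condition
#'
#' A `beat_params` object holds the phenomenological description of how a
#' single isolated cilium beats: the duration of the fast effective stroke,
#' the duration of the slower recovery stroke, the law of the rest interval
#' between beats (lognormal, parameterized by its arithmetic mean and
#' log-scale spread), and the peak-to-trough excursion at the scan line
#' (the generative ciliary bend distance, CBD).
#'
#' Two modes reconcile beat-frequency targets with stroke components:
#'
#' * `"component_matched"`: the configured durations are used verbatim
#'   (up to 4 ms frame quantization). The emergent beat rate is
#'   `1000 / (t_eff + t_rec + interval_mean)` Hz.
#' * `"rate_matched"`: all three components are rescaled by a common factor
#'   so the expected cycle length equals `1000 / target_cbf` ms; used when a
#'   beat-frequency target must be hit exactly.
#'
#' Non-beating (null) conditions are described with `amplitude = 0` and an
#' Ornstein-Uhlenbeck baseline fluctuation (`fluct_sd`, `fluct_tau`).
#'
#' @param t_eff effective-stroke duration, ms (> 0).
#' @param t_rec recovery-stroke duration, ms (> 0).
#' @param interval_mean arithmetic mean of the inter-beat rest interval, ms
#'   (>= 0).
#' @param interval_sigma_log log-scale standard deviation of the lognormal
#'   interval law (dimensionless, >= 0). `0` gives a deterministic interval.
#' @param amplitude peak-to-trough excursion at the scan line, um (>= 0).
#' @param mode `"rate_matched"` or `"component_matched"`.
#' @param target_cbf target beat frequency in Hz; required (and > 0) in
#'   rate-matched mode, ignored otherwise.
#' @param fluct_sd stationary standard deviation of the baseline
#'   Ornstein-Uhlenbeck fluctuation, um (used for null conditions).
#' @param fluct_tau correlation time of the baseline fluctuation, ms.
#' @return An object of class `beat_params`.
#' @examples
#' p <- beat_params(t_eff = 136, t_rec = 38, interval_mean = 234,
#'                  amplitude = 0.57, mode = "component_matched")
#' p
#' @export
beat_params <- function(t_eff, t_rec, interval_mean,
                        interval_sigma_log = 0.45, amplitude,
                        mode = c("rate_matched", "component_matched"),
                        target_cbf = NULL,
                        fluct_sd = 0, fluct_tau = 300) {
  mode <- match.arg(mode)
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(is.numeric(t_eff) && length(t_eff) == 1 && t_eff > 0,
      "t_eff must be a single positive number (ms)")
  chk(is.numeric(t_rec) && length(t_rec) == 1 && t_rec > 0,
      "t_rec must be a single positive number (ms)")
  chk(is.numeric(interval_mean) && length(interval_mean) == 1 &&
        interval_mean >= 0,
      "interval_mean must be a single nonnegative number (ms)")
  chk(is.numeric(interval_sigma_log) && interval_sigma_log >= 0,
      "interval_sigma_log must be >= 0")
  chk(is.numeric(amplitude) && amplitude >= 0, "amplitude must be >= 0")
  chk(is.numeric(fluct_sd) && fluct_sd >= 0, "fluct_sd must be >= 0")
  chk(is.numeric(fluct_tau) && fluct_tau > 0, "fluct_tau must be > 0")
  if (mode == "rate_matched") {
    chk(!is.null(target_cbf) && is.numeric(target_cbf) && target_cbf > 0,
        "target_cbf must be a single positive number (Hz) in rate_matched mode")
  }
  if (length(errs))
    stop("invalid beat parameters:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(
    list(t_eff = t_eff, t_rec = t_rec, interval_mean = interval_mean,
         interval_sigma_log = interval_sigma_log, amplitude = amplitude,
         mode = mode,
         target_cbf = if (mode == "rate_matched") target_cbf else NULL,
         fluct_sd = fluct_sd, fluct_tau = fluct_tau),
    class = "beat_params")
}

#' @export
print.beat_params <- function(x, ...) {
  cat("Beat parameters (", x$mode, ")\n", sep = "")
  cat(sprintf("  effective stroke : %g ms\n", x$t_eff))
  cat(sprintf("  recovery stroke  : %g ms\n", x$t_rec))
  cat(sprintf("  rest interval    : mean %g ms, sigma_log %g\n",
              x$interval_mean, x$interval_sigma_log))
  cat(sprintf("  amplitude (CBD)  : %g um\n", x$amplitude))
  if (!is.null(x$target_cbf))
    cat(sprintf("  target CBF       : %g Hz\n", x$target_cbf))
  if (x$fluct_sd > 0)
    cat(sprintf("  baseline fluct.  : sd %g um, tau %g ms\n",
                x$fluct_sd, x$fluct_tau))
  invisible(x)
}

#' Draw inter-beat rest intervals
#'
#' Intervals follow a lognormal law parameterized by its arithmetic mean
#' `interval_mean` and log-scale sd `interval_sigma_log`
#' (`meanlog = log(m) - sigma^2 / 2`), so the sample mean of many draws
#' converges to `interval_mean`. With `interval_sigma_log = 0` every draw is
#' exactly `interval_mean`.
#'
#' @param params a [beat_params] object (or anything with `interval_mean`
#'   and `interval_sigma_log` fields).
#' @param n number of draws.
#' @param mean_override optional arithmetic mean to use instead of
#'   `params$interval_mean` (used internally by rate matching).
#' @return Numeric vector of `n` nonnegative durations in ms.
#' @export
sample_intervals <- function(params, n, mean_override = NULL) {
  m <- if (is.null(mean_override)) params$interval_mean else mean_override
  if (!is.numeric(m) || m < 0)
    stop("interval mean must be nonnegative", call. = FALSE)
  s <- params$interval_sigma_log
  if (m == 0) return(rep(0, n))
  if (s == 0) return(rep(m, n))
  stats::rlnorm(n, meanlog = log(m) - s^2 / 2, sdlog = s)
}

#' Position within one beat cycle (stroke waveform)
#'
#' Piecewise raised-cosine (smoothstep) ramp: a smooth monotone rise from the
#' baseline 0 to `amplitude` over the effective stroke `[0, t_eff]`, then a
#' smooth monotone fall back to 0 over the recovery stroke
#' `[t_eff, t_eff + t_rec]`; continuous (with continuous velocity) at the
#' peak. Linear in `amplitude`.
#'
#' @param phase_time time since the start of the effective stroke, ms;
#'   vectorized. Must lie in `[0, t_eff + t_rec]`.
#' @param params a [beat_params] object.
#' @param t_eff,t_rec optional duration overrides, ms (used internally after
#'   frame quantization / rate matching).
#' @return Positions in um, same length as `phase_time`.
#' @export
stroke_waveform <- function(phase_time, params,
                            t_eff = params$t_eff, t_rec = params$t_rec) {
  if (any(phase_time < -1e-9 | phase_time > t_eff + t_rec + 1e-9))
    stop("phase_time outside the beat [0, t_eff + t_rec]", call. = FALSE)
  a <- params$amplitude
  eff <- phase_time <= t_eff
  out <- numeric(length(phase_time))
  out[eff] <- a / 2 * (1 - cos(pi * phase_time[eff] / t_eff))
  out[!eff] <- a / 2 * (1 + cos(pi * (phase_time[!eff] - t_eff) / t_rec))
  out
}

## Resolve working kinematics on the acquisition frame grid:
## quantize strokes to whole frames; in rate_matched mode re-solve the rest
## mean after quantization so the expected cycle is exactly 1000/target_cbf.
resolve_kinematics <- function(params, frame_ms = 4) {
  q <- function(x) max(frame_ms, round(x / frame_ms) * frame_ms)
  if (params$mode == "rate_matched") {
    cycle <- 1000 / params$target_cbf
    scale <- cycle / (params$t_eff + params$t_rec + params$interval_mean)
    if (scale <= 0)
      stop("rate_matched: target_cbf implies a non-positive scale factor",
           call. = FALSE)
    t_eff <- q(scale * params$t_eff)
    t_rec <- q(scale * params$t_rec)
    rest_mean <- cycle - t_eff - t_rec
    if (rest_mean < 0)
      stop(sprintf(
        "rate_matched: target_cbf %g Hz is too high for the stroke durations",
        params$target_cbf), call. = FALSE)
  } else {
    t_eff <- q(params$t_eff)
    t_rec <- q(params$t_rec)
    rest_mean <- params$interval_mean
  }
  list(t_eff = t_eff, t_rec = t_rec, rest_mean = rest_mean,
       sigma_log = params$interval_sigma_log,
       amplitude = params$amplitude, frame_ms = frame_ms,
       cycle_mean = t_eff + t_rec + rest_mean)
}

## Exact discretization of an Ornstein-Uhlenbeck process on a uniform grid.
ou_fluctuation <- function(n, sd, tau, dt) {
  if (sd == 0 || n == 0) return(numeric(n))
  a <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  eps <- stats::rnorm(n - 1, 0, innov_sd)
  for (k in seq_len(n - 1)) x[k + 1] <- a * x[k] + eps[k]
  x
}

#' Build a ground-truth beat trajectory
#'
#' Concatenates beats and sampled rest intervals on the 4 ms acquisition grid
#' (250 fps): each cycle is a rest interval drawn from the lognormal law,
#' followed by an effective stroke and a recovery stroke shaped by
#' [stroke_waveform()]. Stroke durations and interval draws are quantized to
#' whole frames so that every true stroke boundary lies on the grid. In
#' rate-matched mode all components are rescaled so the expected cycle equals
#' `1000 / target_cbf` ms. Null conditions (`amplitude = 0`) produce a pure
#' Ornstein-Uhlenbeck baseline fluctuation.
#'
#' The construction starts with a full rest interval at time 0. Pass
#' `warmup_s > 0` to emulate recording a cilium that is already beating: the
#' process is simulated for `warmup_s + duration_s` and the first `warmup_s`
#' seconds are discarded, which removes the start-up bias in peak counts over
#' short records.
#'
#' @param params a [beat_params] object.
#' @param duration_s record duration in seconds (> 0); 2 s is the standard
#'   acquisition length.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @param warmup_s discarded lead-in, seconds.
#' @param fps frames per second of the acquisition grid.
#' @return A `beat_trajectory`: list with `times` (ms), `positions` (um),
#'   `event_log` (data frame of true `effective_start`, `peak_time`,
#'   `recovery_end` in ms for beats whose peak falls in the record) and the
#'   resolved kinematics.
#' @examples
#' p <- beat_params(44, 38, 120, interval_sigma_log = 0, amplitude = 0.98,
#'                  mode = "component_matched")
#' tr <- build_trajectory(p, duration_s = 2)
#' nrow(tr$event_log)
#' @export
build_trajectory <- function(params, duration_s, seed = NULL, warmup_s = 0,
                             fps = 250) {
  stopifnot(inherits(params, "beat_params"))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  frame_ms <- 1000 / fps
  n_frames <- round(duration_s * 1000 / frame_ms)
  warmup_ms <- round(warmup_s * 1000 / frame_ms) * frame_ms
  total_ms <- warmup_ms + n_frames * frame_ms
  times_full <- seq(0, by = frame_ms, length.out = round(total_ms / frame_ms))
  positions <- numeric(length(times_full))
  events <- NULL

  if (params$amplitude > 0) {
    kin <- resolve_kinematics(params, frame_ms)
    beat_len <- kin$t_eff + kin$t_rec
    starts <- numeric(0)
    t_cur <- 0
    while (t_cur <= total_ms) {
      rest <- round(sample_intervals(params, 1, mean_override = kin$rest_mean) /
                      frame_ms) * frame_ms
      t_cur <- t_cur + rest
      if (t_cur > total_ms) break
      starts <- c(starts, t_cur)
      t_cur <- t_cur + beat_len
    }
    for (s0 in starts) {
      i0 <- round(s0 / frame_ms) + 1
      i1 <- min(length(times_full), round((s0 + beat_len) / frame_ms) + 1)
      if (i0 > length(times_full)) next
      idx <- i0:i1
      positions[idx] <- stroke_waveform(times_full[idx] - s0, params,
                                        t_eff = kin$t_eff, t_rec = kin$t_rec)
    }
    events <- data.frame(effective_start = starts,
                         peak_time = starts + kin$t_eff,
                         recovery_end = starts + beat_len)
  } else {
    kin <- list(t_eff = NA_real_, t_rec = NA_real_, rest_mean = NA_real_,
                amplitude = 0, frame_ms = frame_ms, cycle_mean = NA_real_)
    events <- data.frame(effective_start = numeric(0),
                         peak_time = numeric(0),
                         recovery_end = numeric(0))
  }

  if (params$fluct_sd > 0)
    positions <- positions +
      ou_fluctuation(length(positions), params$fluct_sd, params$fluct_tau,
                     frame_ms)

  ## drop the warm-up window (quantized to the frame grid) and re-zero
  shift <- warmup_ms
  keep <- times_full >= shift - 1e-9
  times <- times_full[keep] - shift
  positions <- positions[keep]
  times <- times[seq_len(n_frames)]
  positions <- positions[seq_len(n_frames)]
  if (nrow(events)) {
    events[] <- lapply(events, function(col) col - shift)
    events <- events[events$peak_time >= 0 &
                       events$peak_time <= times[length(times)], ,
                     drop = FALSE]
    rownames(events) <- NULL
  }

  structure(list(times = times, positions = positions, event_log = events,
                 params = params, kinematics = kin, fps = fps),
            class = "beat_trajectory")
}

#' @export
print.beat_trajectory <- function(x, ...) {
  cat(sprintf(
    "Beat trajectory: %d frames (%.3g s at %g fps), %d beats in record\n",
    length(x$times), length(x$times) / x$fps, x$fps, nrow(x$event_log)))
  if (x$params$amplitude > 0)
    cat(sprintf("  amplitude %g um, resolved cycle mean %g ms\n",
                x$params$amplitude, x$kinematics$cycle_mean))
  invisible(x)
}

#' @export
plot.beat_trajectory <- function(x, ...) {
  graphics::plot(x$times, x$positions, type = "l", xlab = "time (ms)",
                 ylab = "position (um)", ...)
  if (nrow(x$event_log))
    graphics::abline(v = x$event_log$peak_time, col = "grey70", lty = 3)
  invisible(x)
}

#' Export a trajectory (and its event log) to CSV
#'
#' Writes `time_ms, position_um` to `path` and the true stroke boundaries to
#' a sidecar `<path base>_events.csv`.
#'
#' @param trajectory a `beat_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(data.frame(time_ms = trajectory$times,
                              position_um = trajectory$positions),
                   path, row.names = FALSE)
  side <- paste0(tools::file_path_sans_ext(path), "_events.csv")
  utils::write.csv(trajectory$event_log, side, row.names = FALSE)
  invisible(path)
}
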