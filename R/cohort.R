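#' Simulate one synthetic cilium recording
#'
#' Builds a ground-truth trajectory for a condition preset and renders it to
#' a frame stack, with trajectory and imaging-noise streams derived
#' deterministically from one seed. By default the recording emulates the
#' standard protocol: 2 s at 250 fps of a cilium that is already beating
#' (1 s discarded warm-up).
#'
#' @param preset a [condition_preset] (see [get_preset()]).
#' @param seed integer seed for this cilium.
#' @param duration_s record duration, s.
#' @param warmup_s discarded lead-in, s; `NULL` (default) uses 1 s or two
#'   mean beat cycles, whichever is longer, so even slow sparse beaters are
#'   recorded in their stationary regime.
#' @param geometry a [cilium_geometry].
#' @param config an [imaging_config].
#' @return A `frame_stack` with the ground-truth trajectory attached.
#' @export
simulate_cilium <- function(preset, seed, duration_s = 2, warmup_s = NULL,
                            geometry = cilium_geometry(),
                            config = imaging_config()) {
  stopifnot(inherits(preset, "condition_preset"))
  if (is.null(warmup_s)) warmup_s <- default_warmup(preset$params)
  traj <- build_trajectory(preset$params, duration_s,
                           seed = derive_seed(seed, "trajectory"),
                           warmup_s = warmup_s, fps = config$fps)
  render_stack(traj, geometry, config,
               seed = derive_seed(seed, "noise"))
}

## Warm-up long enough for the beat process to be effectively stationary at
## the start of the recorded window.
default_warmup <- function(params) {
  if (params$amplitude == 0) return(1)
  kin <- resolve_kinematics(params)
  max(1, 2 * kin$cycle_mean / 1000)
}

#' Quantify one recording end to end
#'
#' Trace extraction, beat detection, CBF/CBD, and stroke segmentation (the
#' latter only when at least one beat was detected).
#'
#' @param stack a `frame_stack`.
#' @inheritParams quantify_stack
#' @param velocity_fraction stroke segmentation threshold, see
#'   [segment_strokes()].
#' @return A list with `measurement` (a `beat_measurement`) and `events`
#'   (a `beat_events` data frame, empty if no beats were detected).
#' @export
measure_cilium <- function(stack, line = NULL, min_prominence = 0.2,
                           min_separation = 20, n_waves = 10,
                           velocity_fraction = 0.1) {
  meas <- quantify_stack(stack, line, min_prominence, min_separation,
                         n_waves)
  events <- if (length(meas$beats$peaks))
    segment_strokes(meas$trace, meas$beats, velocity_fraction)
  else {
    e <- data.frame(effective_start = numeric(0), peak_time = numeric(0),
                    recovery_end = numeric(0), t_eff = numeric(0),
                    t_rec = numeric(0), interval_after = numeric(0),
                    merged = logical(0))
    class(e) <- c("beat_events", "data.frame")
    e
  }
  list(measurement = meas, events = events)
}

#' Simulate and quantify a cohort of cilia for one condition
#'
#' Runs the full simulate -> render -> measure pipeline for `n` cilia, each
#' with a seed derived deterministically from `master_seed`, the preset
#' label and the cilium index.
#'
#' @param preset a [condition_preset].
#' @param master_seed integer master seed.
#' @param n cohort size; defaults to the preset's planned `n_cilia`.
#' @param duration_s record duration per cilium, s.
#' @param warmup_s discarded lead-in per cilium, s (`NULL`: 1 s or two mean
#'   beat cycles, whichever is longer).
#' @param geometry,config rendering settings.
#' @param min_prominence,min_separation,n_waves,velocity_fraction
#'   quantification settings.
#' @return A `cohort_result`: list with `label`, per-cilium `measurements`
#'   data frame (`cilium`, `cbf`, `cbd`, `n_waves_used`, `t_eff_mean`,
#'   `t_rec_mean`), the per-cilium `events` list, and the preset.
#' @export
simulate_cohort <- function(preset, master_seed, n = preset$n_cilia,
                            duration_s = 2, warmup_s = NULL,
                            geometry = cilium_geometry(),
                            config = imaging_config(),
                            min_prominence = 0.2, min_separation = 20,
                            n_waves = 10, velocity_fraction = 0.1) {
  stopifnot(inherits(preset, "condition_preset"))
  rows <- vector("list", n)
  events <- vector("list", n)
  for (i in seq_len(n)) {
    cil_seed <- derive_seed(master_seed, preset$label, i)
    stack <- simulate_cilium(preset, cil_seed, duration_s, warmup_s,
                             geometry, config)
    res <- measure_cilium(stack, NULL, min_prominence, min_separation,
                          n_waves, velocity_fraction)
    ev <- res$events
    keep <- if (nrow(ev)) !ev$merged else logical(0)
    use <- which(keep)[seq_len(min(10, sum(keep)))]
    rows[[i]] <- data.frame(
      cilium = i,
      cbf = res$measurement$cbf,
      cbd = res$measurement$cbd,
      n_waves_used = res$measurement$n_waves_used,
      t_eff_mean = if (length(use)) mean(ev$t_eff[use]) else NA_real_,
      t_rec_mean = if (length(use)) mean(ev$t_rec[use]) else NA_real_)
    events[[i]] <- ev
  }
  structure(list(label = preset$label, preset = preset,
                 measurements = do.call(rbind, rows), events = events,
                 duration_s = duration_s),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d cilia, %.3g s records\n", x$label,
              nrow(x$measurements), x$duration_s))
  print(summarize_condition(x))
  invisible(x)
}

#' Condition-level summary of a quantified cohort
#'
#' Arithmetic means and sample standard deviations (SD 0 by convention for a
#' single cilium) of CBF and CBD; mean stroke durations; pooled inter-beat
#' interval statistics via [summarize_intervals()].
#'
#' @param cohort a `cohort_result` from [simulate_cohort()], or a list with
#'   elements `measurements` (data frame with `cbf`, `cbd`, optionally
#'   `t_eff_mean`, `t_rec_mean`) and `events`.
#' @param label condition label (taken from the cohort if omitted).
#' @return A one-row data frame of class `condition_summary`.
#' @export
summarize_condition <- function(cohort, label = cohort$label) {
  m <- cohort$measurements
  if (is.null(m) || nrow(m) == 0)
    stop("empty cohort: nothing to summarize", call. = FALSE)
  iv <- tryCatch(summarize_intervals(cohort$events),
                 error = function(e) list(mean = NA_real_, min = NA_real_,
                                          max = NA_real_, n_beats = 0L))
  out <- data.frame(
    label = label,
    n_cilia = nrow(m),
    cbf_mean = mean(m$cbf, na.rm = TRUE),
    cbf_sd = sd0(m$cbf),
    cbd_mean = mean(m$cbd, na.rm = TRUE),
    cbd_sd = sd0(m$cbd),
    t_eff_mean = mean(m$t_eff_mean, na.rm = TRUE),
    t_rec_mean = mean(m$t_rec_mean, na.rm = TRUE),
    interval_mean = iv$mean, interval_min = iv$min,
    interval_max = iv$max, n_intervals = iv$n_beats)
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Normalize condition summaries to a reference condition
#'
#' Adds `cbf_ratio` and `cbd_ratio` columns (condition mean divided by the
#' reference condition mean); the reference's own ratios are exactly 1.
#'
#' @param summaries a data frame of stacked [summarize_condition()] rows
#'   (or a list of them).
#' @param reference_label label of the reference condition (default
#'   `"pH7.4"`).
#' @return The summaries data frame with ratio columns added.
#' @export
normalize_to_reference <- function(summaries, reference_label = "pH7.4") {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, summaries)
  ref <- summaries[summaries$label == reference_label, ]
  if (nrow(ref) != 1)
    stop("reference condition '", reference_label,
         "' not present (exactly once) in summaries", call. = FALSE)
  if (!is.finite(ref$cbf_mean) || ref$cbf_mean == 0 ||
      !is.finite(ref$cbd_mean) || ref$cbd_mean == 0)
    stop("reference condition has zero or undefined mean", call. = FALSE)
  summaries$cbf_ratio <- summaries$cbf_mean / ref$cbf_mean
  summaries$cbd_ratio <- summaries$cbd_mean / ref$cbd_mean
  summaries
}
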