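#' Segment each beat into effective stroke, recovery stroke and rest
#'
#' Operationalizes frame-counting of stroke durations with a reproducible
#' velocity-threshold rule. For every detected peak:
#'
#' * `effective_start` is the last frame before the rising speed crosses
#'   `velocity_fraction` times that beat's maximum rising speed at which
#'   the cilium was already moving (the crossing frame itself when the
#'   preceding frame shows no motion);
#' * `recovery_end` is the first frame after the peak at which the position
#'   has returned to within 10% of the beat amplitude above the local rest
#'   baseline and the speed has fallen below the threshold;
#' * durations are frame counts times 4 ms (at 250 fps) — never sub-frame
#'   interpolated;
#' * `interval_after` is the rest time from `recovery_end` to the next
#'   beat's `effective_start` (absent for the last beat).
#'
#' If the next beat starts before the recovery criterion is met, the two
#' beats overlap: the recovery end is clipped to the inter-peak minimum and
#' the event is flagged `merged` rather than silently dropped.
#'
#' @param trace a `position_trace`.
#' @param beats a `beat_peaks` result from [detect_beats()].
#' @param velocity_fraction speed threshold as a fraction of the per-beat
#'   maximum speed (default 0.1).
#' @return A `beat_events` data frame with columns `effective_start`,
#'   `peak_time`, `recovery_end`, `t_eff`, `t_rec`, `interval_after` (all
#'   ms) and `merged`.
#' @export
segment_strokes <- function(trace, beats, velocity_fraction = 0.1) {
  stopifnot(inherits(trace, "position_trace"), inherits(beats, "beat_peaks"))
  p <- beats$peaks
  if (!length(p)) stop("no detected beats to segment", call. = FALSE)
  x <- trace$position_um
  tms <- trace$time_ms
  n <- length(x)
  dt <- 1000 / attr(trace, "fps")
  v <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt

  m <- length(p)
  eff_start <- peak_i <- rec_end <- integer(m)
  merged <- logical(m)
  for (i in seq_len(m)) {
    pk <- p[i]
    ## rising phase: from the preceding trough (or record start) to the peak
    lo <- if (i == 1) 1L else beats$troughs[i]
    rise <- lo:pk
    vmax <- max(v[rise])
    thr <- velocity_fraction * vmax
    ## walk backward from the fastest rising frame through the contiguous
    ## above-threshold run; isolated noise spikes earlier in the rest phase
    ## cannot capture the start
    j <- rise[which.max(v[rise])]
    while (j > lo && v[j - 1L] >= thr) j <- j - 1L
    ## the start is the last frame before the crossing at which the cilium
    ## was already moving; a preceding frame with no motion at all means
    ## the crossing frame itself is the start
    eff_start[i] <- if (j > lo && v[j - 1L] > 1e-12) j - 1L else j

    ## falling phase: from the peak to the next peak (or record end).
    ## Forward differences localize the stop of the recovery exactly on the
    ## frame where motion ceases (a central difference smears the corner).
    hi <- if (i == m) n else p[i + 1]
    fall <- pk:hi
    baseline <- min(x[fall])
    amp <- x[pk] - baseline
    vf <- c((x[-1] - x[-n]) / dt, 0)
    vthr <- velocity_fraction * max(abs(vf[fall]))
    done <- fall[x[fall] <= baseline + 0.1 * amp & abs(vf[fall]) <= vthr &
                   fall > pk]
    if (length(done)) {
      rec_end[i] <- done[1]
    } else {
      mins <- which(x[fall] == baseline)
      rec_end[i] <- fall[mins[length(mins)]]
      merged[i] <- TRUE
    }
    peak_i[i] <- pk
  }

  events <- data.frame(
    effective_start = tms[eff_start],
    peak_time = tms[peak_i],
    recovery_end = tms[rec_end],
    merged = merged)
  events$t_eff <- events$peak_time - events$effective_start
  events$t_rec <- events$recovery_end - events$peak_time
  events$interval_after <- c(events$effective_start[-1] -
                               events$recovery_end[-m], NA_real_)
  if (m > 1) {
    neg <- which(events$interval_after < 0)
    if (length(neg)) {
      events$merged[neg] <- TRUE
      events$interval_after[neg] <- 0
    }
  }
  events <- events[, c("effective_start", "peak_time", "recovery_end",
                       "t_eff", "t_rec", "interval_after", "merged")]
  class(events) <- c("beat_events", "data.frame")
  events
}

#' Pool inter-beat intervals across beats and cilia
#'
#' Arithmetic mean and extremes over all rest intervals, pooled across
#' records/cilia (intervals cut off by record edges are absent and do not
#' contribute).
#'
#' @param events a `beat_events` data frame or a list of them (one per
#'   cilium/record).
#' @return A list with `mean`, `min`, `max` (ms) and `n_beats` (number of
#'   pooled intervals).
#' @export
summarize_intervals <- function(events) {
  if (inherits(events, "data.frame")) events <- list(events)
  iv <- unlist(lapply(events, function(e) e$interval_after))
  iv <- iv[!is.na(iv)]
  if (!length(iv))
    stop("no complete inter-beat intervals to summarize", call. = FALSE)
  list(mean = mean(iv), min = min(iv), max = max(iv),
       n_beats = length(iv))
}

#' Export per-beat events to CSV
#'
#' @param events a `beat_events` data frame (or list of them).
#' @param path output CSV path.
#' @param cilium_id optional id column value(s).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, cilium_id = NULL) {
  if (inherits(events, "data.frame")) events <- list(events)
  if (is.null(cilium_id)) cilium_id <- seq_along(events)
  rows <- do.call(rbind, lapply(seq_along(events), function(i) {
    e <- as.data.frame(events[[i]])
    cbind(cilium_id = cilium_id[i], e)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
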