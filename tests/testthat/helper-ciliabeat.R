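## Shared fixtures and independent oracles, built in code at test time.

with_seed <- withr::with_seed

## Session-level cache so expensive simulated cohorts are computed once and
## shared between invariant and acceptance tests.
.cb_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cb_cache)) assign(key, expr, envir = .cb_cache)
  get(key, envir = .cb_cache)
}

## Wrap arbitrary position samples as a trajectory the renderer accepts
## (used to drive the renderer with waveforms the generator does not
## produce, e.g. sinusoids).
synthetic_trajectory <- function(times, positions, cycle_ms = NA_real_,
                                 fps = 250) {
  structure(list(
    times = times, positions = positions,
    event_log = data.frame(effective_start = numeric(0),
                           peak_time = numeric(0),
                           recovery_end = numeric(0)),
    params = beat_params(40, 40, 0, interval_sigma_log = 0,
                         amplitude = max(c(0, positions)),
                         mode = "component_matched"),
    kinematics = list(t_eff = NA_real_, t_rec = NA_real_,
                      rest_mean = NA_real_, amplitude = max(c(0, positions)),
                      frame_ms = 1000 / fps, cycle_mean = cycle_ms),
    fps = fps), class = "beat_trajectory")
}

## Sinusoidal crossing trace: amplitude a (um), frequency f (Hz). Offset so
## positions are nonnegative like a real crossing coordinate.
sine_trace <- function(f = 5, a = 0.5, duration_s = 2, fps = 250) {
  t <- seq(0, duration_s * 1000 - 1000 / fps, by = 1000 / fps)
  as_position_trace(t, a + a * sin(2 * pi * f * t / 1000), fps = fps)
}

## Independent closed-form Welch t-test (textbook formulas), the oracle the
## package implementation is checked against.
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}

## Independent closed-form one-way fixed-effects ANOVA.
oracle_anova <- function(groups) {
  k <- length(groups); n <- sum(lengths(groups))
  gm <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f, df = c(k - 1, n - k),
       p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

## Pooled-variance two-sample t statistic (for the F = t^2 identity).
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

## Rate-matched pH cohorts used by both the invariant tests and the
## acceptance checks (full pipeline: simulate -> render -> quantify).
ph_series_cohorts <- function(master_seed = 1) {
  cached(paste0("ph_series_", master_seed), {
    labs <- c("pH7.0", "pH7.2", "pH7.4", "pH7.6", "pH7.8", "pH8.0")
    cohorts <- lapply(labs, function(lb)
      simulate_cohort(get_preset(lb, "rate_matched"), master_seed))
    names(cohorts) <- labs
    cohorts
  })
}

## Noise-free deterministic render of a component-matched preset, long
## enough for `n_beats` full beats; returns measurement plus ground truth.
noise_free_component_run <- function(label, n_beats = 12) {
  cached(paste0("nf_", label, "_", n_beats), {
    pre <- get_preset(label, "component_matched")
    pr <- pre$params
    params <- beat_params(pr$t_eff, pr$t_rec, pr$interval_mean,
                          interval_sigma_log = 0, amplitude = pr$amplitude,
                          mode = "component_matched")
    kin <- ciliabeat:::resolve_kinematics(params)
    dur <- ceiling((n_beats + 2) * kin$cycle_mean / 1000)
    traj <- build_trajectory(params, dur)
    stack <- render_stack(traj, config = imaging_config(noise_sd = 0))
    c(measure_cilium(stack), list(truth = traj))
  })
}
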