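test_that("interval law honors its arithmetic mean and spread", {
  p0 <- beat_params(136, 38, 234, interval_sigma_log = 0, amplitude = 0.57,
                    mode = "component_matched")
  expect_equal(with_seed(1, sample_intervals(p0, 50)), rep(234, 50))

  p <- get_preset("pH7.0")$params
  draws <- with_seed(42, sample_intervals(p, 1e5))
  expect_equal(mean(draws), 234, tolerance = 0.01)
  q <- unname(stats::quantile(draws, c(0.025, 0.975)))
  ## central 95% spans roughly [90, 520] ms, consistent with the observed
  ## 112-584 ms spread at pH 7.0
  expect_lt(q[1], 112)
  expect_gt(q[1], 70)
  expect_gt(q[2], 420)
  expect_lt(q[2], 584)
})

test_that("interval sample means match every bundled beating preset", {
  for (pre in preset_table()) {
    if (pre$params$amplitude == 0) next
    p <- pre$params
    draws <- with_seed(derive_seed(7, pre$label), sample_intervals(p, 1e4))
    se <- stats::sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - p$interval_mean), 3 * se + 1e-9,
              label = paste("interval mean for", pre$label))
  }
})

test_that("stroke waveform is a smooth asymmetric ramp, linear in amplitude", {
  p <- beat_params(136, 38, 234, amplitude = 1.45,
                   mode = "component_matched")
  expect_equal(stroke_waveform(0, p), 0)
  expect_equal(stroke_waveform(p$t_eff, p), 1.45)
  expect_equal(stroke_waveform(p$t_eff + p$t_rec, p), 0)
  expect_equal(stroke_waveform(p$t_eff / 2, p), 0.725)
  expect_error(stroke_waveform(-5, p), "phase_time")
  expect_error(stroke_waveform(p$t_eff + p$t_rec + 1, p), "phase_time")

  tt <- seq(0, p$t_eff + p$t_rec, by = 1)
  y <- stroke_waveform(tt, p)
  expect_true(all(diff(y[tt <= p$t_eff]) >= 0))       # monotone rise
  expect_true(all(diff(y[tt >= p$t_eff]) <= 0))       # monotone fall
  p2 <- beat_params(136, 38, 234, amplitude = 2 * 1.45,
                    mode = "component_matched")
  expect_equal(stroke_waveform(tt, p2), 2 * y)        # linearity
})

test_that("deterministic trajectory construction counts beats in closed form", {
  p <- beat_params(44, 38, 120, interval_sigma_log = 0, amplitude = 0.98,
                   mode = "component_matched")
  tr <- build_trajectory(p, 2)
  ## cycle = 120 rest + 44 + 40 (recovery quantized to the 4 ms grid)
  expect_equal(nrow(tr$event_log), 9)
  expect_true(all(tr$event_log$recovery_end <= 2000))
})

test_that("rate-matched construction hits the target cycle exactly", {
  p <- beat_params(44, 38, 120, interval_sigma_log = 0, amplitude = 1,
                   mode = "rate_matched", target_cbf = 5)
  tr <- build_trajectory(p, 2)
  expect_true(all(abs(diff(tr$event_log$peak_time) - 200) < 1e-9))
})

test_that("component-matched emergent rate follows the cycle components", {
  ## pH 7.0 components: 136 + 38 + 234 -> mean cycle about 408 ms
  p <- get_preset("pH7.0", "component_matched")$params
  tr <- build_trajectory(p, 60, seed = 5)
  cycles <- diff(tr$event_log$effective_start)
  expect_equal(mean(cycles), 408, tolerance = 0.05)
  expect_equal(1000 / mean(cycles), 2.45, tolerance = 0.06)
})

test_that("rate-matched peak rate over 60 s is within 3% of target", {
  for (lb in c("pH7.0", "pH8.0")) {
    p <- get_preset(lb, "rate_matched")$params
    tr <- build_trajectory(p, 60, seed = derive_seed(3, lb), warmup_s = 1)
    rate <- nrow(tr$event_log) / 60
    expect_lt(abs(rate - p$target_cbf) / p$target_cbf, 0.03,
              label = paste("peak rate for", lb))
  }
})

test_that("event boundaries sit on the 4 ms grid with baseline positions", {
  p <- get_preset("pH7.4", "component_matched")$params
  tr <- build_trajectory(p, 4, seed = 9)
  ev <- tr$event_log
  expect_true(all(unlist(ev) %% 4 == 0))
  on_grid <- ev$effective_start[ev$effective_start >= 0]
  idx <- on_grid / 4 + 1
  expect_true(all(abs(tr$positions[idx]) < 1e-9))
  rec <- ev$recovery_end[ev$recovery_end <= max(tr$times)]
  expect_true(all(abs(tr$positions[rec / 4 + 1]) < 1e-9))
  ## positions never leave [baseline, amplitude]
  expect_true(all(tr$positions >= -1e-9 &
                    tr$positions <= p$amplitude + 1e-9))
})

test_that("degenerate and inconsistent configurations are rejected", {
  expect_error(beat_params(136, 38, -5, amplitude = 0.5,
                           mode = "component_matched"), "interval_mean")
  expect_error(beat_params(0, 38, 100, amplitude = 0.5,
                           mode = "component_matched"), "t_eff")
  expect_error(beat_params(136, 38, 100, amplitude = 0.5,
                           mode = "rate_matched"), "target_cbf")
  ## a rate target faster than the strokes allow cannot be matched
  p <- beat_params(100, 100, 10, amplitude = 1, mode = "rate_matched",
                   target_cbf = 200)
  expect_error(build_trajectory(p, 2), "too high")
  expect_error(build_trajectory(
    beat_params(40, 40, 50, amplitude = 1, mode = "component_matched"), 0),
    "duration")
})

test_that("trajectories are reproducible from their seed", {
  p <- get_preset("pH7.6", "rate_matched")$params
  t1 <- build_trajectory(p, 2, seed = 11, warmup_s = 1)
  t2 <- build_trajectory(p, 2, seed = 11, warmup_s = 1)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$event_log, t2$event_log)
})
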