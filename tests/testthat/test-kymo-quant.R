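test_that("noise-free trace extraction tracks ground truth to half a pixel", {
  ## sinusoidal crossing, 5 Hz, 0.5 um amplitude
  t <- seq(0, 1996, by = 4)
  truth <- 0.5 + 0.5 * sin(2 * pi * 5 * t / 1000)
  tr <- synthetic_trajectory(t, truth, cycle_ms = 200)
  st <- render_stack(tr, config = imaging_config(noise_sd = 0))
  trace <- extract_trace(st)
  off <- attr(trace, "line")$rest_offset
  expect_lt(max(abs(trace$position_um - (off + truth))), 0.05)
  expect_true(all(trace$quality > 0.9))
})

test_that("degenerate scenes are handled explicitly", {
  ## static filament: constant trace, zero variance
  flat <- synthetic_trajectory(seq(0, 396, by = 4), rep(0.4, 100))
  st <- render_stack(flat, config = imaging_config(noise_sd = 0))
  trace <- extract_trace(st)
  expect_equal(stats::var(trace$position_um), 0)

  ## pure background: an error, not a silent zero trace
  bg <- st
  bg$frames[] <- 200
  expect_error(extract_trace(bg), "no crossing detected")

  ## scan line outside the frame
  expect_error(extract_trace(st, scan_line(c(-5, 2), c(-5, 10))),
               "outside the frame")
})

test_that("beat detection counts prominent peaks with separation", {
  tr <- sine_trace(f = 5, a = 0.5, duration_s = 2)
  b <- detect_beats(tr)
  expect_length(b$peaks, 10)                          # f x T
  expect_equal(compute_cbf(b, 2), 5)

  ## sub-threshold ripple detects nothing
  ripple <- sine_trace(f = 5, a = 0.05, duration_s = 2)
  expect_length(detect_beats(ripple)$peaks, 0)
  expect_equal(compute_cbf(detect_beats(ripple), 2), 0)

  ## two peaks 8 ms apart: only the more prominent survives separation
  x <- rep(0, 100)
  x[40] <- 0.8; x[42] <- 1.0
  tw <- as_position_trace(seq(0, 396, by = 4), x)
  b2 <- detect_beats(tw, min_separation = 20)
  expect_length(b2$peaks, 1)
  expect_equal(tw$position_um[b2$peaks], 1.0)

  expect_error(compute_cbf(b, 0), "record_duration")
})

test_that("bend distance averages complete peak-to-trough waves", {
  tr <- sine_trace(f = 5, a = 0.5, duration_s = 2)
  b <- detect_beats(tr)
  cbd <- compute_cbd(tr, b)
  ## peak-to-trough = 2 x amplitude, up to 4 ms sampling of the extrema
  expect_equal(cbd$cbd, 1.0, tolerance = 0.005)

  ## 12 waves available, 10 requested -> exactly 10 used
  tr12 <- sine_trace(f = 6, a = 0.5, duration_s = 2.2)
  b12 <- detect_beats(tr12)
  expect_gte(length(b12$peaks), 12)
  expect_equal(compute_cbd(tr12, b12, n_waves = 10)$n_waves_used, 10L)

  ## no waves: undefined, flagged distinctly from 0
  none <- detect_beats(sine_trace(a = 0.05))
  out <- compute_cbd(sine_trace(a = 0.05), none)
  expect_true(is.na(out$cbd))
  expect_equal(out$n_waves_used, 0L)
})

test_that("bend distance is invariant to intensity scale and background", {
  p <- beat_params(44, 38, 120, interval_sigma_log = 0, amplitude = 0.98,
                   mode = "component_matched")
  tr <- build_trajectory(p, 2)
  m1 <- quantify_stack(render_stack(
    tr, config = imaging_config(noise_sd = 0)))
  m2 <- quantify_stack(render_stack(
    tr, config = imaging_config(noise_sd = 0, filament_intensity = 10000,
                                background_level = 1500)))
  expect_equal(m1$cbd, m2$cbd, tolerance = 0.01)
  expect_equal(m1$cbf, m2$cbf)
})

test_that("the variance-map helper suggests a usable scan line", {
  p <- beat_params(44, 38, 120, interval_sigma_log = 0, amplitude = 0.98,
                   mode = "component_matched")
  tr <- build_trajectory(p, 2)
  st <- cached("render_ph74_nf_2s", {
    render_stack(tr, config = imaging_config(noise_sd = 0))
  })
  line <- suggest_scan_line(st)
  m <- quantify_stack(st, line)
  expect_equal(m$cbf, nrow(tr$event_log) / 2, tolerance = 0.15)
  expect_gt(m$cbd, 0.7)                 # crosses most of the beat envelope

  flat <- synthetic_trajectory(seq(0, 96, by = 4), rep(0.4, 25))
  stf <- render_stack(flat, config = imaging_config(noise_sd = 0))
  expect_error(suggest_scan_line(stf), "nothing moves")
})

test_that("full quantification recovers a representative single cilium", {
  pre <- get_preset("rep_pH7.0")
  stack <- simulate_cilium(pre, seed = derive_seed(1, "rep", 1))
  m <- quantify_stack(stack)
  expect_lte(abs(m$cbf - 3), 0.5)                     # 3 Hz +- 0.5
  expect_lte(abs(m$cbd - 0.6), 0.06)
})
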