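test_that("posed centerline is anchored, length-preserving and symmetric", {
  g <- cilium_geometry()
  rest <- pose_cilium(g, 0)
  expect_equal(rest[1, ], g$anchor)
  expect_equal(rest[nrow(rest), 2], g$anchor[2])      # straight along base

  bent <- pose_cilium(g, 1.45, n_points = 2000)
  arc <- sum(sqrt(diff(bent[, 1])^2 + diff(bent[, 2])^2))
  expect_lt(abs(arc - g$length) / g$length, 0.01)

  mir <- pose_cilium(g, -1.45, n_points = 2000)
  expect_equal(mir[, 1], bent[, 1], tolerance = 1e-12)
  expect_equal(mir[, 2] - g$anchor[2], -(bent[, 2] - g$anchor[2]),
               tolerance = 1e-12)

  ## the arc crosses the scan line at exactly the requested offset
  x0 <- g$anchor[1] + g$scanline_fraction * g$length
  i <- which.min(abs(bent[, 1] - x0))
  cross_y <- stats::approx(bent[, 1], bent[, 2], xout = x0)$y
  expect_equal(cross_y - g$anchor[2], 1.45, tolerance = 0.01)
})

test_that("rendered stacks are deterministic with the documented shape", {
  p <- beat_params(44, 38, 120, interval_sigma_log = 0, amplitude = 0.98,
                   mode = "component_matched")
  tr <- build_trajectory(p, 2)
  st <- cached("render_ph74_nf_2s", {
    render_stack(tr, config = imaging_config(noise_sd = 0))
  })
  expect_equal(dim(st$frames), c(128L, 128L, 500L))   # duration x fps
  st2 <- render_stack(tr, config = imaging_config(noise_sd = 0))
  expect_identical(st$frames, st2$frames)             # bit-identical

  ## static scene: all frames identical
  flat <- synthetic_trajectory(seq(0, 96, by = 4), rep(0, 25))
  stf <- render_stack(flat, config = imaging_config(noise_sd = 0))
  expect_equal(stf$frames, array(stf$frames[, , 1], dim(stf$frames)))
})

test_that("scan-line intensity maximum tracks the true crossing position", {
  p <- beat_params(44, 38, 120, interval_sigma_log = 0, amplitude = 0.98,
                   mode = "component_matched")
  tr <- build_trajectory(p, 2)
  st <- cached("render_ph74_nf_2s", {
    render_stack(tr, config = imaging_config(noise_sd = 0))
  })
  ## brute-force per-frame argmax along the line, independent of
  ## extract_trace
  line <- default_scan_line(st$geometry)
  px <- st$config$pixel_size
  tt <- seq(0, 1, length.out = 2000)
  sx <- line$a[1] + tt * (line$b[1] - line$a[1])
  sy <- line$a[2] + tt * (line$b[2] - line$a[2])
  i <- pmin(pmax(round(sx / px + 0.5), 1), dim(st$frames)[1])
  j <- pmin(pmax(round(sy / px + 0.5), 1), dim(st$frames)[2])
  for (k in seq(1, 500, by = 7)) {
    prof <- st$frames[, , k][cbind(i, j)]
    am <- tt[which.max(prof)] * line$length
    expect_lt(abs(am - (line$rest_offset + tr$positions[k])), 0.05 + px / 2)
  }
})

test_that("integrated filament brightness is invariant to displacement", {
  cfg <- imaging_config(noise_sd = 0)
  totals <- vapply(c(0, 0.7, 1.45), function(d) {
    tr <- synthetic_trajectory(c(0, 4), c(d, d))
    st <- render_stack(tr, config = cfg)
    sum(st$frames[, , 1] - cfg$background_level)
  }, numeric(1))
  expect_lt(max(abs(totals - totals[1])) / totals[1], 0.01)
})

test_that("aliased or out-of-frame configurations are refused", {
  p <- beat_params(37, 38, 31, interval_sigma_log = 0, amplitude = 1.45,
                   mode = "component_matched")
  tr_slow <- build_trajectory(p, 1, fps = 30)
  expect_error(render_stack(tr_slow, config = imaging_config(fps = 30)),
               "frames per cycle")
  ## a pose leaving the frame names the offending time
  big <- synthetic_trajectory(c(0, 4, 8), c(0, 3, 0))
  expect_error(render_stack(big,
                            geometry = cilium_geometry(anchor = c(1.5, 11.5)),
                            config = imaging_config(noise_sd = 0)),
               "exits the frame at t = 4 ms")
  empty <- synthetic_trajectory(numeric(0), numeric(0))
  expect_error(render_stack(empty, config = imaging_config()), "empty")
})

test_that("TIFF round trip preserves pixels, order and metadata", {
  p <- beat_params(44, 38, 120, interval_sigma_log = 0, amplitude = 0.98,
                   mode = "component_matched")
  tr <- build_trajectory(p, 0.2)
  st <- render_stack(tr, config = imaging_config(), seed = 21)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_identical(back$frames, st$frames)            # lossless
  expect_equal(back$config$fps, 250)
  expect_equal(back$config$pixel_size, 0.1)

  ## single-page file reads as a one-frame stack
  one <- tiff::readTIFF(path, all = TRUE)[[1]]
  p1 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(one, p1, bits.per.sample = 16)
  st1 <- read_stack(p1, fps = 250, pixel_size = 0.1)
  expect_equal(dim(st1$frames)[3], 1L)

  expect_error(read_stack(withr::local_tempfile(fileext = ".tif")),
               "no such")
})
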