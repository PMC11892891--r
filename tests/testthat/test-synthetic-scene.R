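test_that("rendering is deterministic: identical config gives identical stacks", {
  cfg <- scene_config(detector_geometry(32, 32, 0.075, 15.5, 15.5),
                      scan_metadata(0, 0.2, 5),
                      background_base = 20, peaks = list(
                        peak_spec(10, 20, 0.5, 1000)), seed = 17)
  a <- render_stack(cfg)
  b <- render_stack(cfg)
  for (i in seq_along(a$stack$frames))
    expect_identical(a$stack$frames[[i]]$counts, b$stack$frames[[i]]$counts)
  expect_identical(a$truth$lambda, b$truth$lambda)
})

test_that("a zero-peak flat scene renders Poisson counts at the stated mean", {
  b <- 30
  geom <- detector_geometry(512, 512, 0.075, 255.5, 255.5)
  cfg <- scene_config(geom, scan_metadata(0, 0.2, 1), background_base = b,
                      background_decay_px = 1e9, background_floor = 0,
                      seed = 4)
  f <- render_stack(cfg)$stack$frames[[1]]
  n <- length(f$counts)
  # sample mean within 5 standard errors of b
  expect_lt(abs(mean(f$counts) - b), 5 * sqrt(b / n))
  # and Poisson variance ~ mean
  expect_lt(abs(var(as.numeric(f$counts)) / b - 1), 0.05)
})

test_that("a rocking width much narrower than the slice lands on one frame", {
  geom <- detector_geometry(32, 32, 0.075, 15.5, 15.5)
  scan <- scan_metadata(0, 0.2, 10)
  # sigma_phi 0.01 deg << 0.2 deg slice, centred in frame 6
  pk <- peak_spec(16, 16, 1.3, 5000, sigma_phi = 0.01)
  truth <- render_stack(scene_config(geom, scan, background_base = 1,
                                     peaks = list(pk), seed = 1))$truth
  lam <- truth$lambda[1, ]
  expect_gte(lam[7] / sum(lam), 0.99)
})

test_that("per-frame phi masses integrate to the total intensity", {
  # scan covering +/- 4 sigma_phi around the rocking centre
  sigma_phi <- 0.25
  pk <- peak_spec(16, 16, phi_center = 1.0, total_intensity = 1e4,
                  sigma_phi = sigma_phi)
  scan <- scan_metadata(0, 0.2, 10)  # 0..2 deg = +/- 4 sigma around 1.0
  geom <- detector_geometry(32, 32, 0.075, 15.5, 15.5)
  truth <- render_stack(scene_config(geom, scan, background_base = 1,
                                     peaks = list(pk), seed = 1))$truth
  # independent oracle: numeric quadrature of the Gaussian rocking curve
  oracle <- integrate(function(phi)
    pk$total_intensity * dnorm(phi, 1.0, sigma_phi), 0, 2,
    rel.tol = 1e-10)$value
  expect_lt(abs(sum(truth$lambda[1, ]) - oracle) / oracle, 1e-6)
  expect_lt(abs(sum(truth$lambda[1, ]) - 1e4) / 1e4, 1e-4)  # within 0.01%
})

test_that("integrated counts agree with ground truth within Monte Carlo error", {
  geom <- detector_geometry(64, 64, 0.075, 31.5, 31.5)
  scan <- scan_metadata(0, 0.2, 8)
  bg <- 5
  pk <- peak_spec(30.3, 33.8, 0.8, 4e4, sigma_px = 1.5, sigma_phi = 0.2)
  sc <- render_stack(scene_config(geom, scan, background_base = bg,
                                  background_decay_px = 1e9,
                                  background_floor = 0,
                                  peaks = list(pk), seed = 12))
  rows <- 23:39; cols <- 26:42  # +/- 8 px window around the peak
  tot <- sum(vapply(sc$stack$frames, function(f)
    sum(f$counts[rows, cols]), numeric(1)))
  expected <- sum(sc$truth$lambda[1, ]) + bg * length(rows) * length(cols) *
    length(sc$stack$frames)
  se <- sqrt(expected)  # Poisson
  expect_lt(abs(tot - expected), 3 * se)
})

test_that("gap pixels are invalid everywhere and no valid count is negative", {
  stack <- noise_stack(3, 32, 32, gaps = list(c(10, 14, 0, 32)))
  for (f in stack$frames) {
    expect_false(any(f$valid[11:14, ]))
    expect_true(all(f$counts[f$valid] >= 0))
  }
})

test_that("peak centres inside a gap are recorded as occluded", {
  geom <- detector_geometry(32, 32, 0.075, 15.5, 15.5,
                            gap_regions = list(c(10, 14, 0, 32)))
  scan <- scan_metadata(0, 0.2, 2)
  sc <- render_stack(scene_config(
    geom, scan, background_base = 5,
    peaks = list(peak_spec(11.5, 16, 0.2, 500),   # inside the gap stripe
                 peak_spec(25, 16, 0.2, 500)),
    seed = 3))
  expect_identical(sc$truth$peaks$occluded, c(TRUE, FALSE))
})

test_that("presets emulate the benchmark acquisitions", {
  lyso <- scene_preset("lysozyme-like")
  expect_identical(lyso$scan$n_frames, 1800L)
  expect_equal(lyso$scan$osc_width, 0.2)
  expect_equal(total_rotation(lyso$scan), 360)
  expect_identical(attr(lyso, "scale_factor"), 16L)

  rt <- scene_preset("rt-like")
  expect_identical(rt$scan$n_frames, 1200L)
  expect_equal(total_rotation(rt$scan), 240)

  ds <- scene_preset("desk-small", seed = 7)
  expect_identical(ds$geometry$n_rows, 512L)
  expect_identical(ds$scan$n_frames, 40L)
  expect_error(scene_preset("full-size"), "desk-small")
})

test_that("the desk-small preset renders quickly", {
  elapsed <- system.time(render_stack(scene_preset("desk-small", seed = 1)))[["elapsed"]]
  expect_lt(elapsed, 5)
})
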