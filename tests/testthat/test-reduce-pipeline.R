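test_that("2x2 binning sums blocks and conserves counts", {
  f <- new_frame(matrix(1L, 4, 4))
  b <- bin_pixels(f, 2)
  expect_identical(dim(b$counts), c(2L, 2L))
  expect_true(all(b$counts == 4L))
  expect_identical(sum(b$counts), sum(f$counts))

  set.seed(31)
  g <- new_frame(matrix(rpois(48 * 48, 20), 48, 48))
  for (n in c(2L, 3L, 4L)) {
    bb <- bin_pixels(g, n)
    expect_identical(dim(bb$counts), c(48L %/% n, 48L %/% n))
    expect_identical(sum(bb$counts),
                     sum(g$counts[seq_len(48 %/% n * n), seq_len(48 %/% n * n)]))
  }
  expect_error(bin_pixels(f, 5), "dimension")
})

test_that("binning reduces a frame by exactly the square of the factor", {
  f <- new_frame(matrix(0L, 3000, 3000))
  b <- bin_pixels(f, 2)
  expect_identical(dim(b$counts), c(1500L, 1500L))
  expect_identical(length(f$counts) / length(b$counts), 4)
})

test_that("a block with any invalid pixel yields an invalid superpixel", {
  valid <- matrix(TRUE, 4, 4); valid[1, 2] <- FALSE
  f <- new_frame(matrix(3L, 4, 4), valid)
  b <- bin_pixels(f, 2)
  expect_identical(b$valid, matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
  expect_identical(b$counts[1, 1], 0L)  # invalid superpixels carry 0
})

test_that("remainder rows and columns are dropped and recorded", {
  f <- new_frame(matrix(1L, 7, 9))
  b <- bin_pixels(f, 2)
  expect_identical(dim(b$counts), c(3L, 4L))
  expect_identical(attr(b, "rows_dropped"), 1L)
  expect_identical(attr(b, "cols_dropped"), 1L)
})

test_that("bin_metadata updates geometry by pure division", {
  g <- detector_geometry(3000, 3200, 0.075, 1500.0, 1600.0,
                         gap_regions = list(c(100, 110, 0, 3200)))
  s <- scan_metadata(0, 0.2, 100)
  m <- bin_metadata(g, s, 2)
  expect_equal(m$geometry$pixel_size, 0.15)
  expect_equal(m$geometry$beam_center_row, 750.0)
  expect_equal(m$geometry$beam_center_col, 800.0)
  expect_identical(m$geometry$n_rows, 1500L)
  # gap rows [100, 110) map to superpixel rows [50, 55)
  expect_equal(m$geometry$gap_regions[[1]][1:2], c(50, 55))
  # any overlap includes the superpixel: [99, 110) -> [49, 55)
  g2 <- detector_geometry(3000, 3200, 0.075, 1500, 1600,
                          gap_regions = list(c(99, 110, 0, 3200)))
  expect_equal(bin_metadata(g2, s, 2)$geometry$gap_regions[[1]][1:2], c(49, 55))
  # scan untouched
  expect_identical(m$scan, s)
})

test_that("frame summing coarsens the slicing with conserved counts", {
  stack <- tiny_stack(6, 8, 8, fill = 1L)
  s2 <- sum_frames(stack, 2)
  expect_length(s2$frames, 3)
  expect_true(all(s2$frames[[1]]$counts == 2L))
  expect_equal(s2$scan$osc_width, 0.4)
  expect_equal(s2$scan$count_time, stack$scan$count_time * 2)
  expect_equal(s2$scan$osc_start, stack$scan$osc_start)
  expect_identical(sum(sapply(s2$frames, function(f) sum(f$counts))),
                   sum(sapply(stack$frames, function(f) sum(f$counts))))

  # 5 frames summed by 2: 2 output frames, 1 dropped with a warning
  st5 <- tiny_stack(5, 8, 8)
  expect_warning(r <- sum_frames(st5, 2), "dropped")
  expect_length(r$frames, 2)
  expect_identical(attr(r, "frames_dropped"), 1L)
  expect_error(sum_frames(tiny_stack(3), 4), "exceeds")
})

test_that("an 1800-frame series summed by 2 becomes 900 frames at 0.4 deg", {
  geom <- detector_geometry(8, 8, 0.075, 3.5, 3.5)
  scan <- scan_metadata(0, 0.2, 1800)
  frames <- lapply(0:1799, function(i) new_frame(matrix(1L, 8, 8),
                                                 frame_index = i))
  stack <- frame_stack(frames, geom, scan)
  s2 <- sum_frames(stack, 2)
  expect_identical(s2$scan$n_frames, 900L)
  expect_equal(s2$scan$osc_width, 0.4)
  expect_equal(total_rotation(s2$scan), total_rotation(scan))
})

test_that("binning and summing commute exactly", {
  stack <- noise_stack(4, 32, 32, bg = 25, seed = 41,
                       gaps = list(c(10, 12, 0, 32)))
  a <- sum_frames(bin_stack(stack, 2), 2)
  b <- bin_stack(sum_frames(stack, 2), 2)
  for (i in seq_along(a$frames)) {
    expect_identical(a$frames[[i]]$counts, b$frames[[i]]$counts)
    expect_identical(a$frames[[i]]$valid, b$frames[[i]]$valid)
  }
})

test_that("summing guards against 31-bit overflow", {
  stack <- tiny_stack(2, 4, 4, fill = 2000000000L)
  expect_error(sum_frames(stack, 2), "overflow")
})

test_that("16-bit greyscale conversion clips, masks and reports", {
  valid <- matrix(TRUE, 2, 2); valid[2, 2] <- FALSE
  f <- new_frame(matrix(c(70000L, 3L, 65535L, 12L), 2, 2), valid)
  g16 <- to_grey16(f)
  expect_identical(g16$values[1, 1], 65535L)
  expect_identical(g16$clip_count, 1L)
  expect_identical(g16$values[2, 2], 0L)
  expect_identical(g16$mask_payload, valid)
  # identity case below the clip point
  f2 <- new_frame(matrix(0:3, 2, 2))
  expect_identical(to_grey16(f2)$values, f2$counts)
  expect_identical(to_grey16(f2)$clip_count, 0L)
})

test_that("pipeline strings parse and invalid stage orders are rejected", {
  p <- parse_pipeline("bin2,sum2,hcomp:16")
  expect_identical(format(p), "bin2,sum2,hcomp:16")
  expect_identical(unclass(p)[[3]]$scale, 16L)
  expect_error(parse_pipeline("bin2,bin4"), "one BIN")
  expect_error(parse_pipeline("hcomp:4,sum2"), "terminal")
  expect_error(parse_pipeline("byteoffset,hcomp:4"), "one terminal codec")
  expect_error(parse_pipeline("shrink9"), "grammar")
  expect_error(parse_pipeline("j2k:0.5"), "ratio")
  expect_error(parse_pipeline(""), "empty")
})

test_that("BIN and SUM reduce stored samples by the advertised factors", {
  stack <- noise_stack(8, 64, 64, bg = 15, seed = 51)
  cs8 <- compress_pipeline(stack, "bin2,sum2")
  expect_identical(cs8$header$orig_samples / cs8$header$reduced_samples, 8)
  # 8 frames summed by 5: one output group, three frames dropped
  cs20 <- compress_pipeline(stack, "bin2,sum5")
  expect_identical(cs20$header$drops$frames, 3L)
  stack10 <- noise_stack(10, 64, 64, bg = 15, seed = 51)
  cs20 <- compress_pipeline(stack10, "bin2,sum5")
  expect_identical(cs20$header$orig_samples / cs20$header$reduced_samples, 20)
  csa <- compress_pipeline(stack, "bin3,sum4")
  expect_identical(csa$header$orig_samples / csa$header$reduced_samples,
                   (64 * 64 * 8) / (21 * 21 * 2))
})

test_that("the lossless byteoffset pipeline round-trips bit-identically", {
  stack <- noise_stack(3, 48, 48, bg = 40, seed = 61,
                       gaps = list(c(20, 24, 0, 48)))
  rt <- decompress_pipeline(compress_pipeline(stack, "byteoffset"))
  for (i in seq_along(stack$frames)) {
    expect_identical(rt$frames[[i]]$counts, stack$frames[[i]]$counts)
    expect_identical(rt$frames[[i]]$valid, stack$frames[[i]]$valid)
  }
  # no codec at all: raw samples, also identity
  rt2 <- decompress_pipeline(compress_pipeline(stack, "bin2"))
  ref <- bin_pixels(stack$frames[[2]], 2)
  expect_identical(rt2$frames[[2]]$counts, ref$counts)
})

test_that("hcomp scale 0 in a pipeline equals the pure reduction", {
  stack <- noise_stack(4, 32, 32, bg = 30, seed = 71,
                       gaps = list(c(8, 10, 0, 32)))
  rt <- decompress_pipeline(compress_pipeline(stack, "bin2,sum2,hcomp:0"))
  ref <- suppress_sum_warning(sum_frames(bin_stack(stack, 2), 2))
  for (i in seq_along(ref$frames)) {
    expect_identical(rt$frames[[i]]$counts, ref$frames[[i]]$counts)
    expect_identical(rt$frames[[i]]$valid, ref$frames[[i]]$valid)
  }
  expect_equal(rt$scan$osc_width, 0.4)
  expect_identical(rt$geometry$n_rows, 16L)
})

test_that("masked pixels never enter the codec and are restored invalid", {
  stack <- noise_stack(2, 64, 64, bg = 500, seed = 81,
                       gaps = list(c(30, 40, 0, 64)))
  rt <- decompress_pipeline(compress_pipeline(stack, "hcomp:8"))
  expect_identical(rt$frames[[1]]$valid, stack$frames[[1]]$valid)
  expect_true(all(rt$frames[[1]]$counts[!rt$frames[[1]]$valid] == 0L))
  # reconstruction of valid pixels unharmed by the deep gap stripe
  v <- stack$frames[[1]]$valid
  rms <- sqrt(mean((stack$frames[[1]]$counts[v] - rt$frames[[1]]$counts[v])^2))
  expect_lt(rms, 10)  # ~ sqrt(bg)/2 scale error, not sentinel-driven
})

test_that("hcomp reconstruction keeps strong-peak intensities in a reduced stack", {
  cfg <- weak_peak_scene(seed = 6, intensity = 3e4)  # strong peaks
  sc <- render_stack(cfg)
  ref <- suppress_sum_warning(sum_frames(bin_stack(sc$stack, 2), 2))
  tst <- decompress_pipeline(compress_pipeline(sc$stack, "bin2,sum2,hcomp:16"))
  si <- stack_impact(ref, tst, sc$truth)
  rel <- abs(si$peaks$I_after - si$peaks$I_before) / si$peaks$I_before
  expect_true(all(rel < 0.1))
})

test_that("the wavelet stage demands an explicit external codec", {
  stack <- noise_stack(1, 16, 16, bg = 5, seed = 91)
  old <- options(mxsqueeze.wavelet_codec = NULL); on.exit(options(old))
  expect_error(compress_pipeline(stack, "j2k:125"), "options\\(")
  # a registered mock codec flows through the 16-bit greyscale path
  options(mxsqueeze.wavelet_codec = list(
    id = "mock-j2k",
    encode = function(g16, target_ratio)
      memCompress(writeBin(as.integer(g16$values), raw(), size = 4L),
                  type = "gzip"),
    decode = function(blob, shape)
      matrix(readBin(memDecompress(blob, type = "gzip"), "integer",
                     n = shape[1] * shape[2], size = 4L), shape[1], shape[2])))
  cs <- compress_pipeline(stack, "j2k:125")
  expect_identical(cs$codec_variant_id, "wavelet-mock-j2k")
  rt <- decompress_pipeline(cs)
  expect_identical(rt$frames[[1]]$counts, stack$frames[[1]]$counts)
})
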