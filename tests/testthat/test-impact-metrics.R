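test_that("the compression report identities hold exactly", {
  stack <- noise_stack(3, 64, 64, bg = 35, seed = 14)
  cs <- compress_pipeline(stack, "byteoffset")
  rep <- compression_report(stack, cs)
  # byteoffset-only: numerator equals denominator by definition
  expect_identical(rep$ecr, 1)
  expect_identical(rep$lossy_bytes, rep$byte_offset_bytes)
  expect_equal(rep$ecr * rep$baseline_ratio, rep$total_ratio)

  cs2 <- compress_pipeline(stack, "bin2,sum2,hcomp:16")
  rep2 <- compression_report(stack, cs2)
  expect_equal(rep2$ecr * rep2$baseline_ratio, rep2$total_ratio)
  expect_gt(rep2$ecr, 1)
  expect_true(all(c(rep2$raw_bytes, rep2$byte_offset_bytes,
                    rep2$lossy_bytes) > 0))
})

test_that("reduction plus lossless coding multiplies the total ratio", {
  stack <- noise_stack(4, 64, 64, bg = 35, seed = 15)
  plain <- compression_report(stack, compress_pipeline(stack, "byteoffset"))
  reduced <- compression_report(stack,
                                compress_pipeline(stack, "bin2,sum2,byteoffset"))
  # x8 fewer samples, discounted by the byte-offset efficiency change
  expect_gte(reduced$total_ratio / plain$total_ratio, 4)
})

test_that("profiles average the requested rows and respect the mask", {
  # flat background: profile is constant
  f <- new_frame(matrix(7L, 32, 32))
  p <- extract_profile(f, c(15, 15), n_rows = 6, half_width = 5)
  expect_length(p$values, 11)
  expect_true(all(p$values == 7))

  # symmetric noiseless Gaussian peak: symmetric profile
  b <- 1000; h <- 10000; s <- 2.5
  g <- outer(exp(-((0:31 - 15)^2) / (2 * s^2)),
             exp(-((0:31 - 15)^2) / (2 * s^2)))
  f2 <- new_frame(matrix(as.integer(round(b + h * g)), 32, 32))
  p2 <- extract_profile(f2, c(15, 15), n_rows = 5, half_width = 8)
  expect_equal(p2$values, rev(p2$values), tolerance = 1e-6)

  # closed-form oracle: 6-row average = b + h * colfactor * mean(rowfactor)
  p3 <- extract_profile(f2, c(15, 15), n_rows = 6, half_width = 8)
  rows <- 13:18  # rows averaged for n_rows = 6 centred on 15 (0-based)
  rowfac <- mean(exp(-((rows - 15)^2) / (2 * s^2)))
  k <- -8:8
  oracle <- b + h * exp(-(k^2) / (2 * s^2)) * rowfac
  expect_equal(p3$values, oracle, tolerance = 1e-3)

  # fully invalid column flagged missing
  valid <- matrix(TRUE, 32, 32); valid[, 18] <- FALSE  # 0-based column 17
  f4 <- new_frame(matrix(5L, 32, 32), valid)
  p4 <- extract_profile(f4, c(15, 15), n_rows = 6, half_width = 5)
  idx <- 17 - 15 + 5 + 1
  expect_true(is.na(p4$values[idx]))
  expect_true(all(!is.na(p4$values[-idx])))

  expect_error(extract_profile(f, c(2, 2), 6, 8), "window")
})

test_that("peak_impact classifies identity, loss, boost and distortion", {
  swf <- single_weak_frame(seed = 5)
  ref <- swf$frame
  # identity: preserved with zero deltas
  id <- peak_impact(ref, ref, swf$peak)
  expect_identical(id$classification, "preserved")
  expect_equal(id$delta_I, 0)
  expect_equal(id$snr_before, id$snr_after)

  # peak window replaced by a background draw: lost
  set.seed(6)
  flat <- ref
  counts <- flat$counts
  win <- outer((seq_len(128) - 1 - swf$peak$row)^2,
               (seq_len(128) - 1 - swf$peak$col)^2, "+") <= 36
  counts[win] <- rpois(sum(win), 10)
  flat <- new_frame(counts)
  expect_identical(peak_impact(ref, flat, swf$peak)$classification, "lost")

  # peak intensity doubled: boosted
  boosted <- ref
  counts <- boosted$counts
  counts[win] <- counts[win] + as.integer(round(2.2 * (counts[win] - 10)))
  boosted <- new_frame(pmax(counts, 0L))
  expect_identical(peak_impact(ref, boosted, swf$peak)$classification,
                   "boosted")

  expect_error(peak_impact(ref, new_frame(matrix(1L, 8, 8)), swf$peak),
               "geometry")
})

test_that("classification is invariant under a common constant offset", {
  swf <- single_weak_frame(seed = 7)
  ref <- swf$frame
  tst <- swf$reconstruct(16)
  base <- peak_impact(ref, tst, swf$peak)$classification
  refc <- new_frame(ref$counts + 100L)
  tstc <- new_frame(tst$counts + 100L)
  expect_identical(peak_impact(refc, tstc, swf$peak)$classification, base)
})

test_that("an entirely invalid annulus is an error", {
  valid <- matrix(FALSE, 32, 32); valid[14:18, 14:18] <- TRUE
  f <- new_frame(matrix(3L, 32, 32), valid)
  pk <- peak_spec(15, 15, 0, 100, sigma_px = 1)
  expect_error(peak_impact(f, f, pk), "annulus")
})

test_that("stack_impact on identical stacks reports full preservation", {
  sc <- render_stack(weak_peak_scene(seed = 2))
  si <- stack_impact(sc$stack, sc$stack, sc$truth)
  expect_identical(unname(si$class_counts[["preserved"]]), 6)
  expect_identical(si$lost_fraction, 0)
  expect_true(all(abs(si$background_variance_ratio - 1) < 1e-12))
  expect_false(si$over_compressed)
  expect_error(stack_impact(sc$stack, tiny_stack(2), sc$truth), "structure")
})

test_that("over-compression flags a stack whose weak peaks vanish", {
  sc <- render_stack(weak_peak_scene(seed = 2))
  t64 <- decompress_pipeline(compress_pipeline(sc$stack, "hcomp:64"))
  si <- stack_impact(sc$stack, t64, sc$truth)
  expect_gte(si$lost_fraction, 0.5)
  expect_true(si$over_compressed)
})

test_that("real-space R matches closed forms and a brute-force oracle", {
  ref <- array(0:7, c(2, 2, 2))
  expect_identical(real_space_r(ref, ref, "total_density"), 0)
  expect_identical(real_space_r(ref, ref, "variance"), 0)

  # hand-computed oracle for the reversed grid:
  # total: sum|0..7 - 7..0| / sum|0..7| = 32/28; variance: 168/42
  tst <- array(7:0, c(2, 2, 2))
  expect_equal(real_space_r(ref, tst, "total_density"), 32 / 28)
  expect_equal(real_space_r(ref, tst, "variance"), 4)
  expect_equal(real_space_r_avg(ref, tst), (32 / 28 + 4) / 2)

  # constant offset in variance mode: N * c^2 / sum((ref - mean)^2)
  c0 <- 2.5
  expect_equal(real_space_r(ref, ref + c0, "variance"), 8 * c0^2 / 42)

  # errors: shape mismatch, flat reference in variance mode
  expect_error(real_space_r(ref, array(0, c(2, 2, 3))), "shape")
  flat <- array(1, c(2, 2, 2))
  expect_error(real_space_r(flat, ref, "variance"), "flat reference")
  expect_error(real_space_r(array(0, c(2, 2, 2)), ref, "total_density"),
               "zero denominator|no density")

  # density_grid container validates its input
  expect_error(density_grid(matrix(1, 2, 2)), "3-D")
  expect_error(density_grid(array(c(1, NA), c(2, 1, 1))), "finite")
  dg <- density_grid(ref, voxel_size = 0.5)
  expect_equal(real_space_r(dg, density_grid(tst), "variance"), 4)
})

test_that("real_space_r is positive definite in variance mode", {
  set.seed(44)
  ref <- array(rnorm(4^3), c(4, 4, 4))
  for (i in 1:20) {
    tst <- ref + array(rnorm(4^3, sd = runif(1, 0, 2)), c(4, 4, 4))
    r <- real_space_r(ref, tst, "variance")
    expect_gte(r, 0)
    if (!identical(tst, ref)) expect_gt(r, 0)
  }
})
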