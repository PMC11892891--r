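# Quantifying what a compression did: sizes and ratios (including the
# extra compression ratio), reflection profiles, peak survival
# classification, stack-level summaries, and real-space R on density grids.

#' Compression report with extra compression ratio
#'
#' Sizes are measured on payload bytes only (container headers excluded).
#' The extra compression ratio (ECR) is the compression achieved beyond
#' the lossless entropy-limit proxy: the byte-offset-compressed size of
#' the original, as-collected stack divided by the lossy payload size, so
#' that `ecr * baseline_ratio == total_ratio` exactly.
#'
#' @param stack The original `mx_stack` the compression started from.
#' @param cstack The `mx_compressed` produced from it.
#' @return An object of class `mx_report`: `raw_bytes`,
#'   `byte_offset_bytes`, `lossy_bytes` (codec payload),
#'   `container_bytes` (mask + serialized header, reported separately),
#'   `total_ratio`, `baseline_ratio` and `ecr`.
#' @export
compression_report <- function(stack, cstack) {
  raw_bytes <- raw_stack_bytes(stack)
  bo_bytes <- byte_offset_size(stack)
  lossy <- payload_bytes(cstack)
  container <- length(cstack$mask_payload) +
    length(serialize(cstack$header, NULL))
  structure(list(raw_bytes = raw_bytes,
                 byte_offset_bytes = bo_bytes,
                 lossy_bytes = lossy,
                 container_bytes = container,
                 total_ratio = raw_bytes / lossy,
                 baseline_ratio = raw_bytes / bo_bytes,
                 ecr = bo_bytes / lossy),
            class = "mx_report")
}

#' @export
print.mx_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<mx_report> raw %.0f B | byte-offset %.0f B | lossy payload %.0f B\n",
    "  baseline ratio %.2f : 1 | total ratio %.2f : 1 | ECR %.2f : 1\n"),
    x$raw_bytes, x$byte_offset_bytes, x$lossy_bytes,
    x$baseline_ratio, x$total_ratio, x$ecr))
  invisible(x)
}

#' Extract an averaged row profile through a reflection
#'
#' Averages `n_rows` rows centred on the peak and reports the resulting
#' count profile across `2 * half_width + 1` columns, the standard way
#' compression impact on a reflection is displayed (six rows on native
#' frames, three on binned frames where the peak occupies fewer pixels).
#' Invalid pixels are excluded from each column mean; a column whose
#' window is fully invalid is flagged `NA`.
#'
#' @param frame An `mx_frame`.
#' @param center Numeric `c(row, col)`, 0-based pixel units.
#' @param n_rows Number of rows averaged (default 6; use 3 for binned
#'   frames).
#' @param half_width Half-width of the profile in pixels.
#' @return An object of class `mx_profile` with fields `values` (length
#'   `2 * half_width + 1`), `center`, `n_rows_averaged`, `half_width`.
#' @export
extract_profile <- function(frame, center, n_rows = 6L, half_width = 12L) {
  n_rows <- as.integer(n_rows); half_width <- as.integer(half_width)
  r0 <- round(center[1]) + 1L  # to 1-based
  c0 <- round(center[2]) + 1L
  rows <- (r0 - (n_rows - 1L) %/% 2L):(r0 + n_rows %/% 2L)
  cols <- (c0 - half_width):(c0 + half_width)
  if (min(rows) < 1L || max(rows) > nrow(frame$counts) ||
      min(cols) < 1L || max(cols) > ncol(frame$counts))
    stop("profile window does not fit inside the frame")
  sub <- frame$counts[rows, cols, drop = FALSE]
  subv <- frame$valid[rows, cols, drop = FALSE]
  vals <- vapply(seq_along(cols), function(k) {
    v <- sub[subv[, k], k]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  structure(list(values = vals, center = as.numeric(center),
                 n_rows_averaged = n_rows, half_width = half_width),
            class = "mx_profile")
}

#' Classification thresholds for peak-impact analysis
#'
#' @param detect_sigma Detectability floor: a peak is lost when its
#'   background-subtracted intensity fails
#'   `I > detect_sigma * sd_annulus * sqrt(n_window)` (the conventional
#'   I/sigma(I) ~ 3 weak-reflection floor).
#' @param tau_boost Boost threshold: boosted when
#'   `I_after > (1 + tau_boost) * I_before`.
#' @param rho_min Minimum windowed shape correlation before a surviving
#'   peak is called distorted.
#' @param lost_fraction_max Stack-level over-compression flag bound.
#' @return A list of thresholds.
#' @export
impact_thresholds <- function(detect_sigma = 3, tau_boost = 0.5,
                              rho_min = 0.9, lost_fraction_max = 0.2) {
  list(detect_sigma = detect_sigma, tau_boost = tau_boost,
       rho_min = rho_min, lost_fraction_max = lost_fraction_max)
}

# circular window and annulus masks around a (0-based) centre
peak_windows <- function(dimr, dimc, row, col, radius, ann_in, ann_out) {
  d2 <- outer((seq_len(dimr) - 1 - row)^2, (seq_len(dimc) - 1 - col)^2, "+")
  list(window = d2 <= radius^2,
       annulus = d2 > ann_in^2 & d2 <= ann_out^2)
}

peak_stats <- function(frame, peak, thresholds) {
  radius <- max(3 * peak$sigma_px, 2)
  w <- peak_windows(nrow(frame$counts), ncol(frame$counts),
                    peak$row, peak$col, radius, radius + 1, radius + 5)
  win <- w$window & frame$valid
  ann <- w$annulus & frame$valid
  if (!any(ann)) stop("annulus around peak (", peak$row, ", ", peak$col,
                      ") is fully invalid")
  bg_mean <- mean(frame$counts[ann])
  bg_sd <- sd(frame$counts[ann])
  n_win <- sum(win)
  I <- sum(frame$counts[win]) - n_win * bg_mean
  height <- max(frame$counts[win]) - bg_mean
  list(I = I, height = height, bg_mean = bg_mean, bg_sd = bg_sd,
       n_window = n_win,
       snr = I / (bg_sd * sqrt(n_win)),
       window_values = frame$counts[win], window_mask = win)
}

#' Classify the impact of compression on one reflection
#'
#' Measures the background-subtracted integrated intensity in a circular
#' window of radius `3 * sigma_px` (background mean and sigma from a
#' surrounding annulus) before and after compression and classifies the
#' peak as `lost` (the after-peak fails the 3-sigma detectability test),
#' `boosted` (intensity accidentally inflated beyond `1 + tau_boost`
#' times the reference), `distorted` (windowed shape correlation below
#' `rho_min`), or `preserved`. Identical frames classify as preserved
#' with zero deltas, and the classification is invariant under adding the
#' same constant to both frames.
#'
#' @param reference Reference `mx_frame` (before compression).
#' @param test Test `mx_frame` (after compress + decompress), same
#'   geometry.
#' @param peak A [peak_spec()] locating the reflection on these frames.
#' @param thresholds See [impact_thresholds()].
#' @return An object of class `mx_peak_impact` with before/after peak
#'   height, intensity `I`, local background mean and sigma, SNRs, and
#'   `classification`.
#' @export
peak_impact <- function(reference, test, peak,
                        thresholds = impact_thresholds()) {
  if (!identical(dim(reference$counts), dim(test$counts)))
    stop("reference and test frames do not share a geometry")
  before <- peak_stats(reference, peak, thresholds)
  after <- peak_stats(test, peak, thresholds)
  # detectability is judged against the noisier of the two annuli: a codec
  # that flattens the local background must not fake detectability by
  # erasing the noise its own peak has to beat
  sd_detect <- max(after$bg_sd, before$bg_sd)
  detectable <- after$I > thresholds$detect_sigma * sd_detect *
    sqrt(after$n_window)
  shape_cor <- suppressWarnings(
    cor(before$window_values, after$window_values))
  if (is.na(shape_cor)) shape_cor <- 1  # flat window: no shape to distort
  classification <-
    if (!detectable) "lost"
    else if (after$I > (1 + thresholds$tau_boost) * before$I) "boosted"
    else if (shape_cor < thresholds$rho_min) "distorted"
    else "preserved"
  structure(list(
    before = before[c("I", "height", "bg_mean", "bg_sd", "n_window")],
    after = after[c("I", "height", "bg_mean", "bg_sd", "n_window")],
    snr_before = before$snr, snr_after = after$snr,
    shape_cor = shape_cor, delta_I = after$I - before$I,
    classification = classification),
    class = "mx_peak_impact")
}

#' Stack-level compression impact summary
#'
#' Runs [peak_impact()] for every non-occluded ground-truth peak on its
#' dominant frame (the frame carrying the largest expected contribution),
#' after mapping peak coordinates through any binning and the frame index
#' through any summing applied to both stacks. Also reports the per-frame
#' background variance ratio (test / reference over valid pixels) and an
#' over-compression flag raised when the lost fraction exceeds the
#' configured bound.
#'
#' @param reference Reference `mx_stack` (reduction applied, no lossy
#'   codec).
#' @param test Test `mx_stack` (same reduction plus the codec under
#'   study); must match `reference` frame-by-frame in shape and count.
#' @param truth The `mx_truth` from [render_stack()].
#' @param thresholds See [impact_thresholds()].
#' @return An object of class `mx_stack_impact`: per-peak classification
#'   table, per-class counts and fractions, `background_variance_ratio`
#'   per frame, and `over_compressed`.
#' @export
stack_impact <- function(reference, test, truth,
                         thresholds = impact_thresholds()) {
  if (length(reference$frames) != length(test$frames) ||
      !identical(dim(reference$frames[[1]]$counts),
                 dim(test$frames[[1]]$counts)))
    stop("reference and test stacks do not share a structure")
  orig_g <- truth$config$geometry
  bin <- round(orig_g$n_rows / reference$geometry$n_rows)
  sum_m <- round(truth$config$scan$n_frames / length(reference$frames))

  peaks <- truth$peaks
  keep <- which(!peaks$occluded)
  res <- vector("list", length(keep))
  for (idx in seq_along(keep)) {
    p <- keep[idx]
    f_orig <- which.max(truth$lambda[p, ])          # 1-based dominant frame
    f_red <- min((f_orig - 1L) %/% sum_m + 1L, length(reference$frames))
    pk <- peak_spec(row = (peaks$row[p] + 0.5) / bin - 0.5,
                    col = (peaks$col[p] + 0.5) / bin - 0.5,
                    phi_center = peaks$phi_center[p],
                    total_intensity = peaks$total_intensity[p],
                    sigma_px = max(peaks$sigma_px[p] / bin, 0.8),
                    sigma_phi = peaks$sigma_phi[p])
    imp <- peak_impact(reference$frames[[f_red]], test$frames[[f_red]],
                      pk, thresholds)
    res[[idx]] <- data.frame(peak = p, frame = f_red - 1L,
                             I_before = imp$before$I, I_after = imp$after$I,
                             snr_before = imp$snr_before,
                             snr_after = imp$snr_after,
                             classification = imp$classification)
  }
  tab <- do.call(rbind, res)
  classes <- c("preserved", "distorted", "boosted", "lost")
  counts <- vapply(classes, function(cl)
    sum(tab$classification == cl), numeric(1))
  fractions <- counts / max(nrow(tab), 1L)

  bvr <- vapply(seq_along(reference$frames), function(i) {
    v <- reference$frames[[i]]$valid
    var(as.numeric(test$frames[[i]]$counts[v])) /
      var(as.numeric(reference$frames[[i]]$counts[v]))
  }, numeric(1))

  structure(list(peaks = tab, class_counts = counts,
                 class_fractions = fractions,
                 lost_fraction = fractions[["lost"]],
                 background_variance_ratio = bvr,
                 over_compressed =
                   fractions[["lost"]] > thresholds$lost_fraction_max),
            class = "mx_stack_impact")
}

#' @export
print.mx_stack_impact <- function(x, ...) {
  cat(sprintf(
    "<mx_stack_impact> %d peaks: %s | mean bg variance ratio %.3f%s\n",
    nrow(x$peaks),
    paste(sprintf("%s %.0f%%", names(x$class_fractions),
                  100 * x$class_fractions), collapse = ", "),
    mean(x$background_variance_ratio),
    if (x$over_compressed) " | OVER-COMPRESSED" else ""))
  invisible(x)
}

#' Construct a density grid
#'
#' @param values 3-D numeric array of density values (finite).
#' @param voxel_size Voxel spacing (Angstrom), scalar or length-3.
#' @return An object of class `mx_density`.
#' @export
density_grid <- function(values, voxel_size = 1) {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  if (any(!is.finite(values))) stop("density values must be finite")
  structure(list(values = values, voxel_size = as.numeric(voxel_size)),
            class = "mx_density")
}

#' Real-space R between two density grids
#'
#' Two normalizations are provided. `total_density` is the conventional
#' form, `R = sum(|rho_ref - rho_test|) / sum(|rho_ref|)`. `variance` is
#' the custom form in which the denominator is the variance of the
#' reference map rather than its total integrated density:
#' `R = sum((rho_ref - rho_test)^2) / sum((rho_ref - mean(rho_ref))^2)`.
#' [real_space_r_avg()] returns the average of the two modes, the
#' quantity plotted when benchmarking compression strategies.
#'
#' @param reference,test `mx_density` grids (or plain 3-D arrays) of the
#'   same shape.
#' @param mode `"total_density"` or `"variance"`.
#' @return Non-negative real value; 0 iff the grids are equal (given a
#'   non-flat reference in variance mode).
#' @export
real_space_r <- function(reference, test,
                         mode = c("total_density", "variance")) {
  mode <- match.arg(mode)
  ref <- if (inherits(reference, "mx_density")) reference$values else reference
  tst <- if (inherits(test, "mx_density")) test$values else test
  if (!identical(dim(ref), dim(tst)))
    stop("density grids must have matching shapes")
  if (mode == "total_density") {
    den <- sum(abs(ref))
    if (den == 0) stop("zero denominator: reference map has no density")
    sum(abs(ref - tst)) / den
  } else {
    den <- sum((ref - mean(ref))^2)
    if (den == 0) stop("zero denominator: flat reference map in variance mode")
    sum((ref - tst)^2) / den
  }
}

#' @rdname real_space_r
#' @export
real_space_r_avg <- function(reference, test) {
  (real_space_r(reference, test, "total_density") +
     real_space_r(reference, test, "variance")) / 2
}
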