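# Shared fixture builders. Everything is generated in code at test time.

# minimal well-formed stack: small frames, optional gap stripe
tiny_stack <- function(n_frames = 4, nr = 16, nc = 16, fill = 5L,
                       gaps = list()) {
  geom <- detector_geometry(nr, nc, pixel_size = 0.075,
                            beam_center_row = (nr - 1) / 2,
                            beam_center_col = (nc - 1) / 2,
                            gap_regions = gaps)
  scan <- scan_metadata(osc_start = 0, osc_width = 0.2, n_frames = n_frames)
  valid <- valid_plane(geom)
  frames <- lapply(seq_len(n_frames) - 1L, function(i)
    new_frame(matrix(fill, nr, nc), valid, frame_index = i))
  frame_stack(frames, geom, scan)
}

# Poisson stack with no peaks (for codec corpora)
noise_stack <- function(n_frames = 3, nr = 64, nc = 64, bg = 30, seed = 99,
                        gaps = list()) {
  geom <- detector_geometry(nr, nc, pixel_size = 0.075,
                            beam_center_row = (nr - 1) / 2,
                            beam_center_col = (nc - 1) / 2,
                            gap_regions = gaps)
  scan <- scan_metadata(0, 0.2, n_frames)
  cfg <- scene_config(geom, scan, background_base = bg,
                      background_decay_px = 1e9, background_floor = 0,
                      peaks = list(), seed = seed)
  render_stack(cfg)$stack
}

# Weak-peak benchmark scene: flat Poisson background of 10 counts/px,
# six well-separated weak Gaussian reflections whose dominant rotation
# frame carries ~125 expected counts (I/sigma(I) ~ 4 against the 3-sigma
# detectability floor), rocking curves spanning ~2.5 phi slices so that
# frame summing consolidates partials. This is the SNR regime in which a
# scale-4 H-transform pass is harmless and scale 64 swallows peaks.
weak_peak_scene <- function(seed = 2, intensity = 434) {
  geom <- detector_geometry(160, 160, pixel_size = 0.075,
                            beam_center_row = 79.5, beam_center_col = 79.5,
                            gap_regions = list())
  scan <- scan_metadata(0, 0.2, 8)
  set.seed(seed)
  centers_r <- c(35, 35, 80, 80, 125, 125)
  centers_c <- c(50, 110, 50, 110, 50, 110)
  phis <- rep(c(0.6, 1.0), 3)  # centres of the 2nd and 3rd summed pairs
  peaks <- lapply(1:6, function(k)
    peak_spec(row = centers_r[k] + runif(1, -4, 4),
              col = centers_c[k] + runif(1, -4, 4),
              phi_center = phis[k], total_intensity = intensity,
              sigma_px = 1.0, sigma_phi = 0.25))
  scene_config(geom, scan, background_base = 10, background_decay_px = 1e9,
               background_floor = 0, peaks = peaks, seed = seed)
}

# single weak reflection on a flat background, as a frame pair factory:
# returns reference frame and a compress(scale)->decompress closure
single_weak_frame <- function(seed = 5, I_dom = 125, bg = 10, n = 128,
                              row = 59.2, col = 78.7, sigma_px = 1.0) {
  set.seed(seed)
  g <- outer(exp(-((seq_len(n) - 1 - row)^2) / (2 * sigma_px^2)),
             exp(-((seq_len(n) - 1 - col)^2) / (2 * sigma_px^2)))
  mu <- bg + I_dom * g / sum(g)
  frame <- new_frame(matrix(rpois(n * n, mu), n, n))
  list(frame = frame,
       peak = peak_spec(row, col, 0, I_dom, sigma_px = sigma_px,
                        sigma_phi = 0.1),
       reconstruct = function(scale)
         new_frame(pmax(decode_hcomp(encode_hcomp(frame$counts, scale)), 0L)))
}

suppress_sum_warning <- function(expr)
  withCallingHandlers(expr, warning = function(w) invokeRestart("muffleWarning"))
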