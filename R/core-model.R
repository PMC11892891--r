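#' @useDynLib mxsqueeze, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median pnorm rpois runif var sd cor
#' @importFrom utils head tail
NULL

#' Detector geometry
#'
#' Describes a single-panel pixel-array detector. All pixel coordinates in
#' this package are 0-based, row-major, with half-open `[from, to)`
#' intervals; the beam centre is stored in (possibly fractional) pixel
#' units so that binning updates are pure divisions.
#'
#' @param n_rows,n_cols Pixel counts (>= 2).
#' @param pixel_size Edge length of a (square) pixel in mm.
#' @param beam_center_row,beam_center_col Beam centre in 0-based pixel units.
#' @param detector_distance Sample-to-detector distance in mm.
#' @param wavelength X-ray wavelength in Angstrom.
#' @param gap_regions List of gap rectangles, each a numeric vector
#'   `c(row0, row1, col0, col1)` in half-open 0-based pixel coordinates.
#'   Gap pixels (inter-module regions) carry no data and are tracked as
#'   invalid throughout.
#' @return An object of class `mx_geometry`.
#' @export
detector_geometry <- function(n_rows, n_cols, pixel_size,
                              beam_center_row, beam_center_col,
                              detector_distance = 100, wavelength = 1,
                              gap_regions = list()) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 2L || n_cols < 2L) stop("n_rows and n_cols must be >= 2")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  gap_regions <- lapply(gap_regions, function(g) {
    g <- as.numeric(g)
    if (length(g) != 4L) stop("gap rectangle must be c(row0, row1, col0, col1)")
    if (g[1] < 0 || g[2] > n_rows || g[3] < 0 || g[4] > n_cols ||
        g[1] >= g[2] || g[3] >= g[4])
      stop("gap rectangle [", paste(g, collapse = ", "),
           ") does not lie within the frame bounds")
    g
  })
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 pixel_size = as.numeric(pixel_size),
                 beam_center_row = as.numeric(beam_center_row),
                 beam_center_col = as.numeric(beam_center_col),
                 detector_distance = as.numeric(detector_distance),
                 wavelength = as.numeric(wavelength),
                 gap_regions = gap_regions),
            class = "mx_geometry")
}

#' Rotation-scan metadata
#'
#' @param osc_start Starting rotation angle phi in degrees.
#' @param osc_width Rotation per frame (phi slice width) in degrees; fine
#'   phi-slicing collects many narrow slices (e.g. 0.2 degrees per frame).
#' @param n_frames Number of frames in the series.
#' @param count_time Exposure time per frame in seconds.
#' @return An object of class `mx_scan`.
#' @export
scan_metadata <- function(osc_start, osc_width, n_frames, count_time = 0.02) {
  if (osc_width <= 0) stop("osc_width must be > 0")
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  structure(list(osc_start = as.numeric(osc_start),
                 osc_width = as.numeric(osc_width),
                 n_frames = n_frames,
                 count_time = as.numeric(count_time)),
            class = "mx_scan")
}

#' Total rotation range of a scan
#'
#' @param scan An `mx_scan`.
#' @return Total rotation `n_frames * osc_width` in degrees.
#' @export
total_rotation <- function(scan) scan$n_frames * scan$osc_width

#' A single detector frame
#'
#' Holds one exposure as a signed 32-bit photon-count plane plus a boolean
#' validity plane (`FALSE` marks gap or defective pixels). Sentinel values
#' exist only at I/O boundaries; codecs and metrics never see them.
#'
#' @param counts Integer matrix of photon counts.
#' @param valid Logical matrix of the same shape; `FALSE` = gap/defective.
#' @param frame_index 0-based ordinal of this frame in its stack.
#' @return An object of class `mx_frame`.
#' @export
new_frame <- function(counts, valid = NULL, frame_index = 0L) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  storage.mode(counts) <- "integer"
  if (is.null(valid)) valid <- matrix(TRUE, nrow(counts), ncol(counts))
  if (!is.matrix(valid) || !identical(dim(valid), dim(counts)))
    stop("valid must be a logical matrix with the shape of counts")
  storage.mode(valid) <- "logical"
  counts[!valid] <- 0L
  structure(list(counts = counts, valid = valid,
                 frame_index = as.integer(frame_index)),
            class = "mx_frame")
}

#' An ordered rotation-series frame stack
#'
#' @param frames List of [new_frame()] objects sharing one shape and one
#'   validity plane.
#' @param geometry An `mx_geometry`.
#' @param scan An `mx_scan`; `scan$n_frames` must equal `length(frames)`.
#' @return An object of class `mx_stack`.
#' @export
frame_stack <- function(frames, geometry, scan) {
  structure(list(frames = frames, geometry = geometry, scan = scan),
            class = "mx_stack")
}

#' @export
print.mx_stack <- function(x, ...) {
  cat(sprintf("<mx_stack> %d frames of %d x %d px, %.3f deg/frame (total %.1f deg)\n",
              length(x$frames), x$geometry$n_rows, x$geometry$n_cols,
              x$scan$osc_width, total_rotation(x$scan)))
  invisible(x)
}

#' @export
print.mx_frame <- function(x, ...) {
  cat(sprintf("<mx_frame> #%d, %d x %d px, %d invalid px, max count %d\n",
              x$frame_index, nrow(x$counts), ncol(x$counts),
              sum(!x$valid), suppressWarnings(max(x$counts[x$valid], -Inf))))
  invisible(x)
}

#' Logical gap plane implied by a geometry
#'
#' @param geometry An `mx_geometry`.
#' @return Logical matrix, `TRUE` where pixels are valid (outside all gaps).
#' @export
valid_plane <- function(geometry) {
  v <- matrix(TRUE, geometry$n_rows, geometry$n_cols)
  for (g in geometry$gap_regions) {
    # half-open 0-based [row0,row1) x [col0,col1) -> 1-based R indices
    v[(g[1] + 1):g[2], (g[3] + 1):g[4]] <- FALSE
  }
  v
}

#' Validate a frame stack against the domain invariants
#'
#' Validation never raises: every violated invariant is returned as one
#' human-readable string naming the frame index concerned.
#'
#' @param stack An `mx_stack`.
#' @return Character vector of violations; empty when the stack is
#'   well-formed.
#' @export
validate_stack <- function(stack) {
  v <- character(0)
  add <- function(msg) v[[length(v) + 1L]] <<- msg
  g <- stack$geometry
  if (length(stack$frames) != stack$scan$n_frames)
    add(sprintf("stack: %d frames but scan.n_frames = %d",
                length(stack$frames), stack$scan$n_frames))
  ref_valid <- NULL
  for (k in seq_along(stack$frames)) {
    f <- stack$frames[[k]]
    if (!identical(dim(f$counts), c(g$n_rows, g$n_cols))) {
      add(sprintf("frame %d: shape %s does not match geometry %d x %d",
                  f$frame_index, paste(dim(f$counts), collapse = " x "),
                  g$n_rows, g$n_cols))
      next
    }
    if (!identical(dim(f$valid), dim(f$counts)))
      add(sprintf("frame %d: valid plane shape mismatch", f$frame_index))
    if (f$frame_index != k - 1L)
      add(sprintf("frame %d: frame_index is %d, expected %d (strictly increasing from 0)",
                  k - 1L, f$frame_index, k - 1L))
    if (any(f$counts[f$valid] < 0L))
      add(sprintf("frame %d: negative count at a valid pixel", f$frame_index))
    if (is.null(ref_valid)) ref_valid <- f$valid
    else if (!identical(f$valid, ref_valid))
      add(sprintf("frame %d: valid plane differs from frame 0", f$frame_index))
  }
  v
}

#' Default gap sentinel for a stored element width
#'
#' The all-ones bit pattern of the stored dtype, read as a signed integer:
#' `-1` for every width. Real pixel-array detectors flag inter-module gap
#' pixels with this saturation sentinel.
#'
#' @param bytes Element width in bytes (unused beyond documentation; the
#'   all-ones pattern is `-1` at every signed width).
#' @return The sentinel value.
#' @export
default_sentinel <- function(bytes = 4L) -1L

#' Convert an on-disk sentinel-coded plane to a masked frame
#'
#' @param raw_plane Numeric/integer matrix as stored on disk, with gap
#'   pixels carrying `sentinel`.
#' @param sentinel Sentinel value flagging gaps (default [default_sentinel()]).
#' @param frame_index Ordinal for the resulting frame.
#' @return An `mx_frame` with `valid = FALSE` exactly where
#'   `raw_plane == sentinel` and counts 0 there.
#' @export
sentinel_to_mask <- function(raw_plane, sentinel = default_sentinel(),
                             frame_index = 0L) {
  if (!is.matrix(raw_plane)) stop("raw_plane must be a matrix")
  if (sentinel >= 0 && sentinel < 65536)
    warning(sprintf("sentinel %d collides with a plausible photon count (< 2^16)",
                    as.integer(sentinel)))
  valid <- raw_plane != sentinel
  counts <- raw_plane
  counts[!valid] <- 0
  storage.mode(counts) <- "integer"
  new_frame(counts, valid, frame_index = frame_index)
}

#' Convert a masked frame to its sentinel-coded on-disk plane
#'
#' Exact inverse of [sentinel_to_mask()]: the round trip is the identity on
#' any frame whose valid counts never equal the sentinel.
#'
#' @param frame An `mx_frame`.
#' @param sentinel Sentinel value to write at invalid pixels.
#' @return Numeric matrix with `sentinel` at invalid pixels.
#' @export
mask_to_sentinel <- function(frame, sentinel = default_sentinel()) {
  if (any(frame$counts[frame$valid] == sentinel))
    stop("a valid pixel already equals the sentinel value ", sentinel,
         "; encoding would be ambiguous")
  plane <- frame$counts
  storage.mode(plane) <- "double"
  plane[!frame$valid] <- as.numeric(sentinel)
  plane
}
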