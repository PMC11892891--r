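#' CBF byte-offset lossless encoding
#'
#' Implements the CBF byte-offset dialect: each value is stored as its
#' delta from the previous value (initial previous = 0). Deltas in
#' \[-127, 127\] take one signed byte; otherwise the marker `0x80` is
#' emitted followed by a signed 16-bit little-endian delta, escalating
#' through markers `0x8000` (then 32-bit LE) and `0x80000000` (then 64-bit
#' LE). This is the stream the detector control unit of a Pilatus-class
#' detector stores, and the baseline against which extra compression
#' ratios are measured.
#'
#' @param values Numeric vector of integers (exact up to 2^53).
#' @param dtype_tag Original element width in bytes, recorded in the blob
#'   so raw sizes can be reconstructed (4 for the detectors modelled here).
#' @return An object of class `bo_blob` with fields `payload` (raw
#'   vector), `n_values` and `dtype_tag` (original element width in bytes,
#'   4 by default).
#' @seealso [decode_byte_offset()], [byte_offset_size()]
#' @export
encode_byte_offset <- function(values, dtype_tag = 4L) {
  values <- as.numeric(values)
  structure(list(payload = .bo_encode(values),
                 n_values = length(values),
                 dtype_tag = as.integer(dtype_tag)),
            class = "bo_blob")
}

#' Decode a byte-offset blob
#'
#' Exact inverse of [encode_byte_offset()]:
#' `decode_byte_offset(encode_byte_offset(x))` reproduces `x` element-wise.
#' A truncated payload raises an error naming the byte offset reached.
#'
#' @param blob A `bo_blob` (or a raw vector together with `n_values`).
#' @param n_values Element count, required when `blob` is a raw vector.
#' @return Numeric vector of decoded integers.
#' @export
decode_byte_offset <- function(blob, n_values = NULL) {
  if (inherits(blob, "bo_blob")) {
    payload <- blob$payload
    n_values <- blob$n_values
  } else {
    payload <- blob
    if (is.null(n_values)) stop("n_values is required for a raw payload")
  }
  .bo_decode(payload, as.numeric(n_values))
}

# row-major raster of a frame's sentinel-substituted plane, i.e. the
# single-stream CBF convention (fastest dimension = columns)
frame_raster <- function(frame, sentinel = default_sentinel()) {
  as.vector(t(mask_to_sentinel(frame, sentinel)))
}

#' Byte-offset payload size of a stack
#'
#' Encodes each frame's sentinel-substituted row-major raster in frame
#' order and sums the payload bytes. This is the lossless baseline size
#' used as the denominator input for extra compression ratios; ratios are
#' computed on payload bytes only, excluding container headers.
#'
#' @param stack An `mx_stack`.
#' @param sentinel Gap sentinel substituted before encoding.
#' @return Total payload bytes (0 for an empty stack).
#' @export
byte_offset_size <- function(stack, sentinel = default_sentinel()) {
  if (length(stack$frames) == 0L) return(0)
  sum(vapply(stack$frames, function(f)
    length(.bo_encode(frame_raster(f, sentinel))), numeric(1)))
}

#' Raw (uncompressed) byte size of a stack
#'
#' @param stack An `mx_stack`.
#' @param bytes_per_pixel Stored element width; detector pipelines in this
#'   problem store 4-byte integer pixels.
#' @return Total bytes of the uncompressed pixel stream.
#' @export
raw_stack_bytes <- function(stack, bytes_per_pixel = 4L) {
  if (length(stack$frames) == 0L) return(0)
  n <- sum(vapply(stack$frames, function(f) length(f$counts), numeric(1)))
  n * bytes_per_pixel
}
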