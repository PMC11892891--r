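# Integer H-transform (Haar pyramid) codec with a quantization scale,
# modelling the Hcompress family of lossy astronomy codecs.

# padded square power-of-two size for a plane
hpad_size <- function(nr, nc) 2L^as.integer(ceiling(log2(max(nr, nc, 2L))))

# pad by edge replication to an N x N plane (avoids sharp padding edges
# injecting spurious high-frequency coefficients)
hpad <- function(plane, N) {
  nr <- nrow(plane); nc <- ncol(plane)
  ri <- c(seq_len(nr), rep(nr, N - nr))
  ci <- c(seq_len(nc), rep(nc, N - nc))
  plane[ri, ci, drop = FALSE]
}

#' Forward integer H-transform
#'
#' Recursive 2x2 block transform: each block `[[p00, p01], [p10, p11]]`
#' yields the four combinations `h0 = p00+p01+p10+p11`,
#' `hx = (p10+p11)-(p00+p01)`, `hy = (p01+p11)-(p00+p10)` and
#' `hc = p11-p10-p01+p00`; the `h0` values form the next level's input.
#' No integer division is performed at any level (the divisions are
#' deferred entirely to the inverse, where they are exact), so the
#' transform is exactly invertible on integer input. Non-square and
#' non-power-of-two planes are padded by edge replication and cropped on
#' inversion.
#'
#' @param plane Integer (or exact-integer numeric) matrix.
#' @return An object of class `htransform_plane` with fields
#'   `coefficients` (padded square coefficient plane), `n_levels`
#'   (pyramid depth, `ceiling(log2(max(dim)))`) and `original_shape`.
#' @export
h_forward <- function(plane) {
  if (length(plane) == 0L) stop("plane must be non-empty")
  plane <- matrix(as.numeric(plane), nrow(plane), ncol(plane))
  N <- hpad_size(nrow(plane), ncol(plane))
  n_levels <- as.integer(log2(N))
  coef <- .htrans_forward(hpad(plane, N), n_levels)
  structure(list(coefficients = coef, n_levels = n_levels,
                 original_shape = c(nrow(plane), ncol(plane))),
            class = "htransform_plane")
}

#' Inverse integer H-transform
#'
#' Exact inverse of [h_forward()] on unquantized coefficients; on
#' quantized input it returns the reconstruction implied by the
#' dequantized coefficients, rounded to integers and cropped to the
#' original shape.
#'
#' @param ht An `htransform_plane`.
#' @return Integer matrix of the original shape.
#' @export
h_inverse <- function(ht) {
  N <- nrow(ht$coefficients)
  if (ncol(ht$coefficients) != N || 2L^ht$n_levels != N)
    stop("inconsistent n_levels/shape: ", ht$n_levels, " levels for ",
         N, " x ", ncol(ht$coefficients), " coefficients")
  rec <- .htrans_inverse(ht$coefficients, ht$n_levels)
  out <- round(rec[seq_len(ht$original_shape[1]),
                   seq_len(ht$original_shape[2]), drop = FALSE])
  storage.mode(out) <- "integer"
  out
}

# quantization step for every coefficient position of an N x N pyramid:
# detail coefficients produced at pyramid level l (l = 0 finest) use step
# scale * 2^l, which equalizes each level's reconstruction-error
# contribution under the unnormalized (deferred-division) transform. The
# DC coefficient at (1, 1) is never quantized so the reconstruction keeps
# the plane's total count (and hence the background mean).
hquant_steps <- function(N, scale) {
  steps <- matrix(1, N, N)
  if (scale >= 2) {
    m <- N
    lev <- 0L
    while (m > 1L) {
      h <- m %/% 2L
      s <- scale * 2^lev
      steps[seq_len(h), (h + 1L):m] <- s
      steps[(h + 1L):m, seq_len(m)] <- s
      m <- h
      lev <- lev + 1L
    }
  }
  steps
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

hcomp_variant_id <- "hconv1-zzvarint-deflate"

#' Encode a plane with the H-transform codec
#'
#' Applies [h_forward()], quantizes every non-DC coefficient by
#' `round_half_away_from_zero(c / step)` (no quantization at scale 0 or 1;
#' the DC coefficient is never quantized), and entropy-codes the quantized
#' coefficient raster with zigzag-varint serialization followed by
#' DEFLATE. The entropy stage is recorded in `codec_variant_id`; the
#' bitstream is this package's own dialect, not the astronomy program's.
#'
#' @param plane Integer matrix (mask-free: invalid pixels must be filled
#'   before encoding, see [compress_pipeline()]).
#' @param scale Integer quantization scale >= 0. Scales 0 and 1 are
#'   lossless; larger scales discard more background detail.
#' @return An object of class `hcomp_blob`.
#' @export
encode_hcomp <- function(plane, scale) {
  scale <- as.integer(scale)
  if (scale < 0) stop("scale must be >= 0")
  ht <- h_forward(plane)
  N <- nrow(ht$coefficients)
  q <- ht$coefficients / hquant_steps(N, scale)
  q <- round_half_away(q)
  payload <- memCompress(.zz_encode(as.vector(q)), type = "gzip")
  structure(list(scale = scale, payload = payload,
                 n_levels = ht$n_levels,
                 original_shape = ht$original_shape,
                 codec_variant_id = hcomp_variant_id),
            class = "hcomp_blob")
}

#' Decode an H-transform blob
#'
#' Dequantizes (multiplies by the per-level step), inverts the transform
#' and crops; deterministic, and bit-exact when the blob was produced at
#' scale 0 or 1.
#'
#' @param blob An `hcomp_blob`.
#' @return Integer matrix of the original shape.
#' @export
decode_hcomp <- function(blob) {
  if (!identical(blob$codec_variant_id, hcomp_variant_id))
    stop("unknown codec_variant_id: ", blob$codec_variant_id)
  N <- 2L^blob$n_levels
  q <- tryCatch(
    .zz_decode(memDecompress(blob$payload, type = "gzip"), N * N),
    error = function(e) stop("corrupted hcomp payload: ", conditionMessage(e)))
  coef <- matrix(q, N, N) * hquant_steps(N, blob$scale)
  h_inverse(structure(list(coefficients = coef, n_levels = blob$n_levels,
                           original_shape = blob$original_shape),
                      class = "htransform_plane"))
}
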