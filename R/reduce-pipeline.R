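# Reduction operators (pixel binning, frame summing, 16-bit greyscale
# conversion) and pipeline composition with metadata propagation.

#' Bin pixels n x n within a frame
#'
#' Each output superpixel is the sum of its `n` x `n` source block (2 x 2
#' binning replaces each even-numbered pixel of each even-numbered row by
#' the sum of itself and its three neighbours, reducing the pixel count by
#' a factor of four). A superpixel is invalid iff any source pixel in its
#' block is invalid. Trailing remainder rows/columns that do not fill a
#' block are dropped; the drop is recorded in attributes
#' `rows_dropped`/`cols_dropped`.
#'
#' @param frame An `mx_frame`.
#' @param n Integer binning factor >= 2.
#' @return A binned `mx_frame` of shape `(floor(rows/n), floor(cols/n))`.
#' @export
bin_pixels <- function(frame, n) {
  n <- as.integer(n)
  if (n < 2L) stop("binning factor n must be >= 2")
  nr <- nrow(frame$counts); nc <- ncol(frame$counts)
  if (n > nr || n > nc)
    stop("binning factor ", n, " exceeds a frame dimension (", nr, " x ", nc, ")")
  nr2 <- nr %/% n; nc2 <- nc %/% n
  crop_r <- seq_len(nr2 * n); crop_c <- seq_len(nc2 * n)
  blocksum <- function(m) {
    m <- m[crop_r, crop_c, drop = FALSE]
    # fold rows then columns through dim() reshaping; sums stay integer-exact
    m <- array(m, dim = c(n, nr2, nc2 * n))
    m <- colSums(m)                       # nr2 x (nc2 * n)
    m <- array(t(m), dim = c(n, nc2, nr2))
    t(colSums(m))                         # nr2 x nc2
  }
  counts <- blocksum(matrix(as.numeric(frame$counts), nr, nc))
  nbad <- blocksum(matrix(as.numeric(!frame$valid), nr, nc))
  out <- new_frame(matrix(as.integer(counts), nr2, nc2),
                   valid = nbad == 0, frame_index = frame$frame_index)
  attr(out, "rows_dropped") <- nr - nr2 * n
  attr(out, "cols_dropped") <- nc - nc2 * n
  out
}

#' Update geometry and scan metadata for n x n binning
#'
#' Pixel size is multiplied by `n`; pixel counts are floor-divided; the
#' beam centre (pixel units) is divided by `n`; gap rectangles are mapped
#' to superpixel coordinates with any overlap included
#' (`[floor(from/n), ceiling(to/n))`). The scan is unchanged.
#'
#' @param geometry An `mx_geometry`.
#' @param scan An `mx_scan`.
#' @param n Integer binning factor >= 2.
#' @return List with updated `geometry` and `scan`.
#' @export
bin_metadata <- function(geometry, scan, n) {
  n <- as.integer(n)
  if (n < 2L) stop("binning factor n must be >= 2")
  nr2 <- geometry$n_rows %/% n; nc2 <- geometry$n_cols %/% n
  gaps <- lapply(geometry$gap_regions, function(g) {
    c(floor(g[1] / n), min(ceiling(g[2] / n), nr2),
      floor(g[3] / n), min(ceiling(g[4] / n), nc2))
  })
  gaps <- Filter(function(g) g[1] < g[2] && g[3] < g[4], gaps)
  geom <- detector_geometry(
    nr2, nc2, pixel_size = geometry$pixel_size * n,
    beam_center_row = geometry$beam_center_row / n,
    beam_center_col = geometry$beam_center_col / n,
    detector_distance = geometry$detector_distance,
    wavelength = geometry$wavelength, gap_regions = gaps)
  list(geometry = geom, scan = scan)
}

# apply binning to a whole stack, updating metadata
bin_stack <- function(stack, n) {
  frames <- lapply(stack$frames, bin_pixels, n = n)
  meta <- bin_metadata(stack$geometry, stack$scan, n)
  out <- frame_stack(frames, meta$geometry, meta$scan)
  attr(out, "rows_dropped") <- attr(frames[[1]], "rows_dropped")
  attr(out, "cols_dropped") <- attr(frames[[1]], "cols_dropped")
  out
}

#' Sum groups of m consecutive frames
#'
#' Output frame `j` is the pixel-wise sum of input frames
#' `j*m ... j*m + m - 1` (0-based), coarsening the phi slicing m-fold:
#' `osc_width` and `count_time` are multiplied by `m`, `n_frames` becomes
#' `floor(n/m)`. Remainder frames are dropped with a warning and the drop
#' recorded in attribute `frames_dropped`. Invalid pixels stay invalid;
#' summed counts stay 32-bit signed and overflow beyond 31 bits raises.
#'
#' @param stack An `mx_stack`.
#' @param m Integer summing factor >= 2.
#' @return An `mx_stack` with `floor(n/m)` frames.
#' @export
sum_frames <- function(stack, m) {
  m <- as.integer(m)
  if (m < 2L) stop("summing factor m must be >= 2")
  n <- length(stack$frames)
  if (m > n) stop("summing factor ", m, " exceeds the ", n, "-frame stack")
  n2 <- n %/% m
  dropped <- n - n2 * m
  if (dropped > 0)
    warning(dropped, " trailing frame(s) dropped by SUM", m,
            " (stack length not divisible)")
  valid <- stack$frames[[1]]$valid
  frames <- vector("list", n2)
  for (j in seq_len(n2)) {
    acc <- matrix(0, nrow(valid), ncol(valid))
    for (k in seq_len(m))
      acc <- acc + stack$frames[[(j - 1L) * m + k]]$counts
    if (any(acc[valid] > .Machine$integer.max))
      stop("summed counts overflow 31 bits in output frame ", j - 1L)
    frames[[j]] <- new_frame(matrix(as.integer(acc), nrow(acc), ncol(acc)),
                             valid, frame_index = j - 1L)
  }
  scan <- scan_metadata(osc_start = stack$scan$osc_start,
                        osc_width = stack$scan$osc_width * m,
                        n_frames = max(n2, 1L),
                        count_time = stack$scan$count_time * m)
  scan$n_frames <- n2
  out <- frame_stack(frames, stack$geometry, scan)
  attr(out, "frames_dropped") <- dropped
  out
}

#' Convert a frame to 16-bit greyscale
#'
#' Wavelet codecs from the imaging industry consume 16-bit greyscale
#' input; counts are clipped to `[0, 65535]` with the clip count reported,
#' and invalid pixels are written as 0 with the mask carried separately.
#' (An 8-bit path is deliberately not provided: it discards too much
#' dynamic range for diffraction data.)
#'
#' @param frame An `mx_frame`.
#' @return An object of class `grey16_image` with fields `values`
#'   (integer matrix <= 65535), `clip_count` and `mask_payload` (logical
#'   matrix).
#' @export
to_grey16 <- function(frame) {
  v <- frame$counts
  clip <- sum(v[frame$valid] > 65535L)
  v[v > 65535L] <- 65535L
  v[v < 0L] <- 0L
  v[!frame$valid] <- 0L
  structure(list(values = v, clip_count = as.integer(clip),
                 mask_payload = frame$valid),
            class = "grey16_image")
}

# ---------------------------------------------------------------------------
# Pipeline specification
# ---------------------------------------------------------------------------

#' Build and validate a compression pipeline specification
#'
#' A pipeline is an ordered list of stages: at most one `BIN(n)` and one
#' `SUM(m)` reduction stage, which must precede the (at most one,
#' terminal) codec stage `HCOMP(scale)`, `WAVELET(target_ratio)` or
#' `BYTEOFFSET`.
#'
#' @param stages List of stage descriptors as produced by
#'   [parse_pipeline()], each `list(kind =, ...)` with `kind` one of
#'   `"bin"`, `"sum"`, `"hcomp"`, `"wavelet"`, `"byteoffset"`.
#' @return An object of class `mx_pipeline`.
#' @export
pipeline_spec <- function(stages) {
  kinds <- vapply(stages, `[[`, character(1), "kind")
  ok <- c("bin", "sum", "hcomp", "wavelet", "byteoffset")
  if (any(!kinds %in% ok))
    stop("unknown stage kind(s): ", paste(setdiff(kinds, ok), collapse = ", "))
  if (sum(kinds == "bin") > 1L) stop("at most one BIN stage is allowed")
  if (sum(kinds == "sum") > 1L) stop("at most one SUM stage is allowed")
  codec <- kinds %in% c("hcomp", "wavelet", "byteoffset")
  if (sum(codec) > 1L) stop("at most one terminal codec stage is allowed")
  if (any(codec) && which(codec) != length(kinds))
    stop("the codec stage must be terminal (BIN/SUM precede codecs)")
  for (s in stages) {
    if (s$kind == "bin" && (is.null(s$n) || s$n < 2))
      stop("BIN requires an integer factor n >= 2")
    if (s$kind == "sum" && (is.null(s$m) || s$m < 2))
      stop("SUM requires an integer factor m >= 2")
    if (s$kind == "hcomp" && (is.null(s$scale) || s$scale < 0))
      stop("HCOMP requires an integer scale >= 0")
    if (s$kind == "wavelet" && (is.null(s$target_ratio) || s$target_ratio <= 1))
      stop("WAVELET requires a target compression ratio > 1")
  }
  structure(stages, class = "mx_pipeline")
}

#' Parse a pipeline string
#'
#' Grammar: comma-separated stages `bin<n>`, `sum<m>`, `hcomp:<scale>`,
#' `j2k:<ratio>`, `byteoffset`, e.g. `"bin2,sum2,hcomp:16"` (the pipeline
#' written BIN2_SUM2_HCOMP16).
#'
#' @param text Pipeline string.
#' @return An `mx_pipeline`.
#' @export
parse_pipeline <- function(text) {
  parts <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop("empty pipeline string")
  stages <- lapply(parts, function(p) {
    if (grepl("^bin[0-9]+$", p))
      list(kind = "bin", n = as.integer(sub("^bin", "", p)))
    else if (grepl("^sum[0-9]+$", p))
      list(kind = "sum", m = as.integer(sub("^sum", "", p)))
    else if (grepl("^hcomp:[0-9]+$", p))
      list(kind = "hcomp", scale = as.integer(sub("^hcomp:", "", p)))
    else if (grepl("^j2k:[0-9.]+$", p))
      list(kind = "wavelet", target_ratio = as.numeric(sub("^j2k:", "", p)))
    else if (p == "byteoffset")
      list(kind = "byteoffset")
    else
      stop("unknown pipeline stage '", p, "'; grammar: bin<n>, sum<m>, ",
           "hcomp:<scale>, j2k:<ratio>, byteoffset")
  })
  pipeline_spec(stages)
}

#' @export
format.mx_pipeline <- function(x, ...) {
  paste(vapply(unclass(x), function(s) switch(
    s$kind,
    bin = paste0("bin", s$n), sum = paste0("sum", s$m),
    hcomp = paste0("hcomp:", s$scale),
    wavelet = paste0("j2k:", s$target_ratio), byteoffset = "byteoffset"),
    character(1)), collapse = ",")
}

#' @export
print.mx_pipeline <- function(x, ...) {
  cat("<mx_pipeline>", format(x), "\n"); invisible(x)
}

# external wavelet codec adapter: a list(encode =, decode =, id =)
# registered by the user via options(mxsqueeze.wavelet_codec = ...).
wavelet_codec <- function() {
  cdc <- getOption("mxsqueeze.wavelet_codec", NULL)
  if (is.null(cdc) || !is.function(cdc$encode) || !is.function(cdc$decode))
    stop("WAVELET stage requested but no external JPEG-2000 codec is ",
         "configured. Register one with\n  options(mxsqueeze.wavelet_codec = ",
         "list(encode = <fn(grey16, target_ratio) -> raw>,\n       ",
         "decode = <fn(raw, shape) -> integer matrix>, id = \"<codec id>\"))\n",
         "There is no silent fallback.")
  cdc
}

# ---------------------------------------------------------------------------
# Pipeline application
# ---------------------------------------------------------------------------

#' Apply a compression pipeline to a stack
#'
#' BIN/SUM stages restructure the stack (with metadata propagated through
#' [bin_metadata()] and [sum_frames()]); the terminal codec stage then
#' encodes each resulting frame: `hcomp:<scale>` through the H-transform
#' codec (invalid pixels are pre-filled with the median of valid 5 x 5
#' neighbours and restored as invalid afterwards, so sentinels never enter
#' the wavelet transform), `byteoffset` losslessly, and `j2k:<ratio>`
#' through [to_grey16()] and an externally registered wavelet codec (an
#' error with registration instructions if none is configured). Without a
#' codec stage frames are stored as raw 32-bit samples.
#'
#' @param stack An `mx_stack`.
#' @param spec An `mx_pipeline` or pipeline string for [parse_pipeline()].
#' @return An object of class `mx_compressed`: self-describing header
#'   (pipeline, original and reduced geometry/scan, drop/clip records),
#'   losslessly coded valid plane, per-frame codec payload blobs and the
#'   `codec_variant_id`.
#' @export
compress_pipeline <- function(stack, spec) {
  if (is.character(spec)) spec <- parse_pipeline(spec)
  if (!inherits(spec, "mx_pipeline")) spec <- pipeline_spec(spec)
  orig_geometry <- stack$geometry
  orig_scan <- stack$scan
  orig_samples <- raw_stack_bytes(stack, 1L)

  drops <- list(rows = 0L, cols = 0L, frames = 0L)
  codec <- NULL
  for (s in unclass(spec)) {
    if (s$kind == "bin") {
      stack <- bin_stack(stack, s$n)
      drops$rows <- attr(stack, "rows_dropped")
      drops$cols <- attr(stack, "cols_dropped")
    } else if (s$kind == "sum") {
      stack <- withCallingHandlers(
        sum_frames(stack, s$m),
        warning = function(w) invokeRestart("muffleWarning"))
      drops$frames <- attr(stack, "frames_dropped")
    } else codec <- s
  }

  valid <- if (length(stack$frames)) stack$frames[[1]]$valid else
    valid_plane(stack$geometry)
  clip_count <- 0L
  variant <- "raw32-le"
  blobs <- vector("list", length(stack$frames))

  if (is.null(codec)) {
    blobs <- lapply(stack$frames, function(f)
      writeBin(as.integer(as.vector(t(f$counts))), raw(), size = 4L,
               endian = "little"))
  } else if (codec$kind == "byteoffset") {
    variant <- "cbf-byteoffset"
    blobs <- lapply(stack$frames, function(f)
      .bo_encode(frame_raster(f)))
  } else if (codec$kind == "hcomp") {
    variant <- hcomp_variant_id
    blobs <- lapply(stack$frames, function(f) {
      filled <- .fill_invalid_median(matrix(as.numeric(f$counts),
                                            nrow(f$counts), ncol(f$counts)),
                                     f$valid)
      encode_hcomp(filled, codec$scale)
    })
  } else if (codec$kind == "wavelet") {
    cdc <- wavelet_codec()
    variant <- paste0("wavelet-", cdc$id)
    blobs <- lapply(stack$frames, function(f) {
      g16 <- to_grey16(f)
      clip_count <<- clip_count + g16$clip_count
      cdc$encode(g16, codec$target_ratio)
    })
  }

  header <- list(
    format_version = 1L,
    pipeline = format(spec),
    orig_geometry = orig_geometry, orig_scan = orig_scan,
    geometry = stack$geometry, scan = stack$scan,
    orig_samples = orig_samples,
    reduced_samples = raw_stack_bytes(stack, 1L),
    dtype = "int32", bytes_per_pixel = 4L,
    drops = drops, clip_count = clip_count)

  structure(list(header = header,
                 mask_payload = pack_mask(valid),
                 blobs = blobs,
                 codec_variant_id = variant),
            class = "mx_compressed")
}

# lossless bit-packed mask coding (deflated)
pack_mask <- function(valid) {
  memCompress(packBits(c(as.vector(valid), logical((-length(valid)) %% 8)),
                       type = "raw"), type = "gzip")
}

unpack_mask <- function(payload, nr, nc) {
  bits <- as.logical(rawToBits(memDecompress(payload, type = "gzip")))
  matrix(bits[seq_len(nr * nc)], nr, nc)
}

#' Decompress a compressed stack
#'
#' Returns the stack at the reduced geometry (binning and summing are not
#' inverted); codec stages are decoded, the valid plane is restored, and
#' the metadata reflects every recorded transformation. Lossy
#' reconstructions are clamped at zero so counts stay non-negative.
#'
#' @param cstack An `mx_compressed`.
#' @return An `mx_stack`.
#' @export
decompress_pipeline <- function(cstack) {
  h <- cstack$header
  g <- h$geometry
  valid <- unpack_mask(cstack$mask_payload, g$n_rows, g$n_cols)
  variant <- cstack$codec_variant_id
  decode_one <- function(blob) {
    if (variant == "raw32-le") {
      t(matrix(readBin(blob, "integer", n = g$n_rows * g$n_cols, size = 4L,
                       endian = "little"), g$n_cols, g$n_rows))
    } else if (variant == "cbf-byteoffset") {
      plane <- t(matrix(.bo_decode(blob, g$n_rows * g$n_cols),
                        g$n_cols, g$n_rows))
      plane[!valid] <- 0
      plane
    } else if (variant == hcomp_variant_id) {
      pmax(decode_hcomp(blob), 0L)
    } else if (startsWith(variant, "wavelet-")) {
      cdc <- wavelet_codec()
      cdc$decode(blob, c(g$n_rows, g$n_cols))
    } else stop("unknown codec_variant_id: ", variant)
  }
  frames <- vector("list", length(cstack$blobs))
  for (i in seq_along(frames)) {
    plane <- decode_one(cstack$blobs[[i]])
    frames[[i]] <- new_frame(matrix(as.integer(plane), g$n_rows, g$n_cols),
                             valid, frame_index = i - 1L)
  }
  frame_stack(frames, g, h$scan)
}

#' Total codec payload bytes of a compressed stack
#'
#' Payload only (per-frame codec blobs); the mask and header are container
#' overhead and reported separately by [compression_report()].
#'
#' @param cstack An `mx_compressed`.
#' @return Bytes.
#' @export
payload_bytes <- function(cstack) {
  sum(vapply(cstack$blobs, function(b)
    if (is.raw(b)) length(b) else length(b$payload), numeric(1)))
}
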