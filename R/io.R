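# Readers/writers: native stack container (MXS), single-image CBF with
# byte-offset payload, 16-bit greyscale TIFF, single-HDU integer FITS,
# and the MXZ compressed container. All binary fields are little-endian
# except FITS, whose standard mandates big-endian data.

write_kv <- function(con, key, value) {
  writeLines(sprintf("%s: %s", key, paste(format(value, digits = 17),
                                          collapse = " ")), con)
}

geometry_to_kv <- function(con, g, prefix = "") {
  write_kv(con, paste0(prefix, "n_rows"), g$n_rows)
  write_kv(con, paste0(prefix, "n_cols"), g$n_cols)
  write_kv(con, paste0(prefix, "pixel_size"), g$pixel_size)
  write_kv(con, paste0(prefix, "beam_center_row"), g$beam_center_row)
  write_kv(con, paste0(prefix, "beam_center_col"), g$beam_center_col)
  write_kv(con, paste0(prefix, "detector_distance"), g$detector_distance)
  write_kv(con, paste0(prefix, "wavelength"), g$wavelength)
  write_kv(con, paste0(prefix, "n_gaps"), length(g$gap_regions))
  for (i in seq_along(g$gap_regions))
    write_kv(con, paste0(prefix, "gap", i), g$gap_regions[[i]])
}

kv_get <- function(kv, key, required = TRUE) {
  if (!key %in% names(kv)) {
    if (required) stop("required attribute '", key, "' missing")
    return(NULL)
  }
  as.numeric(strsplit(trimws(kv[[key]]), "\\s+")[[1]])
}

kv_geometry <- function(kv, prefix = "") {
  ngap <- kv_get(kv, paste0(prefix, "n_gaps"))
  gaps <- lapply(seq_len(ngap), function(i) kv_get(kv, paste0(prefix, "gap", i)))
  detector_geometry(
    kv_get(kv, paste0(prefix, "n_rows")), kv_get(kv, paste0(prefix, "n_cols")),
    pixel_size = kv_get(kv, paste0(prefix, "pixel_size")),
    beam_center_row = kv_get(kv, paste0(prefix, "beam_center_row")),
    beam_center_col = kv_get(kv, paste0(prefix, "beam_center_col")),
    detector_distance = kv_get(kv, paste0(prefix, "detector_distance")),
    wavelength = kv_get(kv, paste0(prefix, "wavelength")),
    gap_regions = gaps)
}

kv_scan <- function(kv, prefix = "") {
  scan_metadata(osc_start = kv_get(kv, paste0(prefix, "osc_start")),
                osc_width = kv_get(kv, paste0(prefix, "osc_width")),
                n_frames = kv_get(kv, paste0(prefix, "n_frames")),
                count_time = kv_get(kv, paste0(prefix, "count_time")))
}

scan_to_kv <- function(con, s, prefix = "") {
  write_kv(con, paste0(prefix, "osc_start"), s$osc_start)
  write_kv(con, paste0(prefix, "osc_width"), s$osc_width)
  write_kv(con, paste0(prefix, "n_frames"), s$n_frames)
  write_kv(con, paste0(prefix, "count_time"), s$count_time)
}

# read "key: value" lines up to a terminator line
read_kv_block <- function(con, stop_line) {
  kv <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of header")
    if (line == stop_line) break
    m <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(m) == 3L) kv[trimws(m[2])] <- m[3]
  }
  kv
}

#' Write / read a frame stack in the native MXS container
#'
#' A self-describing, minimal rotation-series layout: a text header block
#' (`MXSTACK 1`, geometry and scan attributes as `key: value` lines,
#' terminated by `DATA`) followed by the frame cube as little-endian
#' signed 32-bit row-major rasters with gap pixels carrying the sentinel.
#' The write-then-read round trip is bit-identical, including the mask.
#'
#' @param stack An `mx_stack`.
#' @param path File path.
#' @param sentinel Gap sentinel stored on disk.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns
#'   the `mx_stack`. A missing required attribute raises an error naming
#'   it.
#' @export
write_stack <- function(stack, path, sentinel = default_sentinel()) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- textConnection("hdrtxt", "w", local = TRUE)
  writeLines("MXSTACK 1", hdr)
  geometry_to_kv(hdr, stack$geometry)
  scan_to_kv(hdr, stack$scan)
  write_kv(hdr, "sentinel", sentinel)
  write_kv(hdr, "dtype", "int32")
  writeLines("DATA", hdr)
  close(hdr)
  writeChar(paste0(paste(hdrtxt, collapse = "\n"), "\n"), con, eos = NULL)
  for (f in stack$frames)
    writeBin(as.integer(as.vector(t(mask_to_sentinel(f, sentinel)))), con,
             size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "MXSTACK 1")) stop("not an MXS stack container: ", path)
  kv <- read_kv_block(con, "DATA")
  geometry <- kv_geometry(kv)
  scan <- kv_scan(kv)
  sentinel <- kv_get(kv, "sentinel")
  npx <- geometry$n_rows * geometry$n_cols
  frames <- vector("list", scan$n_frames)
  for (i in seq_len(scan$n_frames)) {
    raster <- readBin(con, "integer", n = npx, size = 4L, endian = "little")
    if (length(raster) < npx) stop("stack data truncated at frame ", i - 1L)
    plane <- t(matrix(raster, geometry$n_cols, geometry$n_rows))
    frames[[i]] <- suppressWarnings(
      sentinel_to_mask(plane, sentinel, frame_index = i - 1L))
  }
  frame_stack(frames, geometry, scan)
}

# ---------------------------------------------------------------------------
# Single-image CBF (documented subset) with byte-offset payload
# ---------------------------------------------------------------------------

cbf_binary_magic <- as.raw(c(0x0C, 0x1A, 0x04, 0xD5))

#' Write / read a single-image CBF file
#'
#' Writes the documented miniCBF-style subset: dimensions, pixel size and
#' oscillation in `# key: value` header comments, and the pixel raster as
#' a `x-CBF_BYTE_OFFSET` binary section whose payload is produced by this
#' package's byte-offset codec. Reading a file whose conversions tag
#' names any other compression raises an error.
#'
#' @param frame An `mx_frame`.
#' @param path File path.
#' @param geometry,scan Optional `mx_geometry`/`mx_scan` whose pixel size
#'   and oscillation are recorded in the header.
#' @param sentinel Gap sentinel substituted into the raster.
#' @return `write_frame_cbf` returns `path` invisibly; `read_frame_cbf`
#'   returns the `mx_frame` with gap pixels re-read as invalid.
#' @export
write_frame_cbf <- function(frame, path, geometry = NULL, scan = NULL,
                            sentinel = default_sentinel()) {
  raster <- as.vector(t(mask_to_sentinel(frame, sentinel)))
  payload <- .bo_encode(raster)
  nr <- nrow(frame$counts); nc <- ncol(frame$counts)
  hdr <- c(
    "###CBF: VERSION 1.5 (mxsqueeze)",
    "",
    sprintf("data_frame_%05d", frame$frame_index),
    "",
    if (!is.null(geometry))
      sprintf("# Pixel_size %.6e m x %.6e m",
              geometry$pixel_size / 1000, geometry$pixel_size / 1000),
    if (!is.null(scan)) sprintf("# Start_angle %.4f deg.", scan$osc_start),
    if (!is.null(scan)) sprintf("# Angle_increment %.4f deg.", scan$osc_width),
    sprintf("# Sentinel %d", as.integer(sentinel)),
    "",
    "_array_data.data",
    ";",
    "--CIF-BINARY-FORMAT-SECTION--",
    "Content-Type: application/octet-stream;",
    "     conversions=\"x-CBF_BYTE_OFFSET\"",
    "Content-Transfer-Encoding: BINARY",
    sprintf("X-Binary-Size: %d", length(payload)),
    "X-Binary-ID: 1",
    "X-Binary-Element-Type: \"signed 32-bit integer\"",
    "X-Binary-Element-Byte-Order: LITTLE_ENDIAN",
    sprintf("X-Binary-Number-of-Elements: %d", nr * nc),
    sprintf("X-Binary-Size-Fastest-Dimension: %d", nc),
    sprintf("X-Binary-Size-Second-Dimension: %d", nr),
    "X-Binary-Size-Padding: 0",
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\r\n"), "\r\n"), con, eos = NULL)
  writeBin(cbf_binary_magic, con)
  writeBin(payload, con)
  writeChar("\r\n--CIF-BINARY-FORMAT-SECTION----\r\n;\r\n", con, eos = NULL)
  invisible(path)
}

#' @rdname write_frame_cbf
#' @export
read_frame_cbf <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # locate the binary section marker
  idx <- which(bytes == cbf_binary_magic[1])
  start <- NA_integer_
  for (i in idx) {
    if (i + 3 <= length(bytes) &&
        identical(bytes[i:(i + 3)], cbf_binary_magic)) { start <- i; break }
  }
  if (is.na(start)) stop("no CBF binary section found in ", path)
  header <- rawToChar(bytes[seq_len(start - 1L)])
  get_field <- function(pattern) {
    m <- regmatches(header, regexec(pattern, header))[[1]]
    if (length(m) < 2L) return(NA)
    m[2]
  }
  conv <- get_field("conversions=\"([^\"]+)\"")
  if (is.na(conv) || conv != "x-CBF_BYTE_OFFSET")
    stop("unsupported CBF compression tag: ",
         if (is.na(conv)) "<missing>" else conv)
  n_elem <- as.integer(get_field("X-Binary-Number-of-Elements:\\s*([0-9]+)"))
  nc <- as.integer(get_field("X-Binary-Size-Fastest-Dimension:\\s*([0-9]+)"))
  nr <- as.integer(get_field("X-Binary-Size-Second-Dimension:\\s*([0-9]+)"))
  psize <- as.integer(get_field("X-Binary-Size:\\s*([0-9]+)"))
  sentinel <- get_field("# Sentinel (-?[0-9]+)")
  sentinel <- if (is.na(sentinel)) default_sentinel() else as.integer(sentinel)
  if (any(is.na(c(n_elem, nc, nr, psize))))
    stop("incomplete CBF binary header in ", path)
  payload <- bytes[(start + 4L):(start + 3L + psize)]
  raster <- .bo_decode(payload, n_elem)
  plane <- t(matrix(raster, nc, nr))
  fidx <- get_field("data_frame_([0-9]+)")
  suppressWarnings(sentinel_to_mask(
    plane, sentinel,
    frame_index = if (is.na(fidx)) 0L else as.integer(fidx)))
}

# ---------------------------------------------------------------------------
# 16-bit greyscale TIFF (via the tiff package)
# ---------------------------------------------------------------------------

#' Write / read a 16-bit greyscale TIFF
#'
#' Lossless round trip of a [to_grey16()] image; the clip count is
#' recorded in a trailing annotation of the file (ignored by ordinary
#' TIFF readers, recovered by [read_grey16_tiff()]). Reading a file that
#' is not 16-bit greyscale raises an error (the 8-bit path is
#' deliberately excluded: it discards too much dynamic range).
#'
#' @param image A `grey16_image`.
#' @param path File path.
#' @return `write_grey16_tiff` returns `path` invisibly;
#'   `read_grey16_tiff` returns a `grey16_image` (with an all-valid mask:
#'   TIFF carries no mask plane).
#' @export
write_grey16_tiff <- function(image, path) {
  tiff::writeTIFF(image$values / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  con <- file(path, "ab")
  writeChar(sprintf("\nmxsqueeze-clip-count=%d\n", image$clip_count), con,
            eos = NULL)
  close(con)
  invisible(path)
}

#' @rdname write_grey16_tiff
#' @export
read_grey16_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits) || bits != 16L)
    stop("not a 16-bit greyscale TIFF (bits per sample: ",
         if (is.null(bits)) "unknown" else bits, ")")
  if (length(dim(img)) != 2L)
    stop("not a greyscale TIFF: ", length(dim(img)), " channels")
  clip <- 0L
  tail_bytes <- readBin(path, "raw", file.size(path))
  hit <- grepRaw("mxsqueeze-clip-count=[0-9]+", tail_bytes, value = TRUE)
  if (length(hit))
    clip <- as.integer(sub("mxsqueeze-clip-count=", "", rawToChar(hit)))
  vals <- matrix(as.integer(img), nrow(img), ncol(img))
  structure(list(values = vals, clip_count = clip,
                 mask_payload = matrix(TRUE, nrow(img), ncol(img))),
            class = "grey16_image")
}

# ---------------------------------------------------------------------------
# Minimal single-HDU integer FITS
# ---------------------------------------------------------------------------

fits_card <- function(key, value, comment = NULL) {
  v <- if (is.character(value)) sprintf("%-20s", sprintf("'%s'", value))
  else sprintf("%20s", format(value))
  txt <- sprintf("%-8s= %s", key, v)
  if (!is.null(comment)) txt <- paste0(txt, " / ", comment)
  sprintf("%-80s", substr(txt, 1, 80))
}

#' Write / read a single-plane integer FITS image
#'
#' Minimal FITS for interoperability with astronomy codecs: one primary
#' HDU, `BITPIX` 16 or 32, big-endian data padded to 2880-byte blocks,
#' and a provenance `COMMENT` card. Reading a multi-extension file
#' returns the first image plane with a warning.
#'
#' @param image Integer matrix, or a `grey16_image` (written as
#'   `BITPIX = 16`).
#' @param path File path.
#' @param bitpix 16 or 32 (bits per stored pixel, signed).
#' @return `write_fits` returns `path` invisibly; `read_fits` returns an
#'   integer matrix with attribute `bitpix`.
#' @export
write_fits <- function(image, path, bitpix = NULL) {
  if (inherits(image, "grey16_image")) {
    if (is.null(bitpix)) bitpix <- 16L
    # BITPIX 16 is signed: the standard unsigned-16 convention is BZERO 32768
    plane <- image$values
  } else {
    if (is.null(bitpix)) bitpix <- 32L
    plane <- image
  }
  bitpix <- as.integer(bitpix)
  if (!bitpix %in% c(16L, 32L)) stop("bitpix must be 16 or 32")
  bzero <- if (bitpix == 16L) 32768 else 0
  cards <- c(
    fits_card("SIMPLE", "T"),
    fits_card("BITPIX", bitpix),
    fits_card("NAXIS", 2L),
    fits_card("NAXIS1", ncol(plane)),   # fastest axis = columns
    fits_card("NAXIS2", nrow(plane)),
    fits_card("BZERO", bzero),
    fits_card("BSCALE", 1),
    sprintf("%-80s", "COMMENT   written by the mxsqueeze diffraction compression toolkit"),
    sprintf("%-80s", "END"))
  # fix SIMPLE card: logical T, not a quoted string
  cards[1] <- sprintf("%-80s", sprintf("%-8s= %20s", "SIMPLE", "T"))
  header <- paste(cards, collapse = "")
  pad <- (-nchar(header)) %% 2880
  header <- paste0(header, strrep(" ", pad))
  stored <- as.vector(t(plane)) - bzero
  lim <- 2^(bitpix - 1)
  if (any(stored < -lim | stored > lim - 1))
    stop("pixel values do not fit BITPIX ", bitpix)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeBin(as.integer(stored), con, size = bitpix %/% 8L, endian = "big")
  nbytes <- length(stored) * (bitpix %/% 8L)
  padb <- (-nbytes) %% 2880
  if (padb > 0) writeBin(raw(padb), con)
  invisible(path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  header_end <- NA_integer_
  pos <- 1L
  kv <- list()
  repeat {
    if (pos + 79L > length(bytes)) stop("FITS header has no END card")
    card <- rawToChar(bytes[pos:(pos + 79L)])
    key <- trimws(substr(card, 1, 8))
    if (key == "END") { header_end <- pos + 79L; break }
    if (grepl("=", card)) {
      val <- trimws(sub("/.*$", "", substr(card, 11, 80)))
      kv[[key]] <- val
    }
    pos <- pos + 80L
  }
  data_start <- (ceiling(header_end / 2880) * 2880) + 1L
  bitpix <- as.integer(kv$BITPIX)
  if (!bitpix %in% c(16L, 32L)) stop("unsupported BITPIX: ", kv$BITPIX)
  nc <- as.integer(kv$NAXIS1); nr <- as.integer(kv$NAXIS2)
  bzero <- if (is.null(kv$BZERO)) 0 else as.numeric(kv$BZERO)
  n <- nr * nc
  vals <- readBin(bytes[data_start:length(bytes)], "integer", n = n,
                  size = bitpix %/% 8L, endian = "big")
  data_bytes <- ceiling(n * (bitpix %/% 8L) / 2880) * 2880
  if (length(bytes) > data_start - 1L + data_bytes)
    warning("multi-extension FITS: returning the first image plane only")
  plane <- t(matrix(vals + bzero, nc, nr))
  storage.mode(plane) <- "integer"
  attr(plane, "bitpix") <- bitpix
  plane
}

# ---------------------------------------------------------------------------
# MXZ native compressed container
# ---------------------------------------------------------------------------

write_section <- function(con, bytes) {
  writeBin(as.integer(length(bytes)), con, size = 4L, endian = "little")
  if (length(bytes)) writeBin(bytes, con)
}

read_section <- function(con) {
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(n) == 0L) stop("MXZ container truncated")
  readBin(con, "raw", n = n)
}

#' Write / read the MXZ compressed container
#'
#' A text header block (format version, pipeline string, original and
#' current geometry/scan, codec variant, drop/clip records) followed by
#' length-prefixed little-endian binary sections: the mask payload, then
#' one blob per frame. The container is self-describing:
#' [decompress_pipeline()] needs nothing else.
#'
#' @param cstack An `mx_compressed`.
#' @param path File path.
#' @return `write_mxz` returns `path` invisibly; `read_mxz` the
#'   `mx_compressed`.
#' @export
write_mxz <- function(cstack, path) {
  h <- cstack$header
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- textConnection("hdrtxt", "w", local = TRUE)
  writeLines("MXZ 1", hdr)
  write_kv(hdr, "pipeline", h$pipeline)
  write_kv(hdr, "codec_variant_id", cstack$codec_variant_id)
  geometry_to_kv(hdr, h$orig_geometry, "orig_")
  scan_to_kv(hdr, h$orig_scan, "orig_")
  geometry_to_kv(hdr, h$geometry)
  scan_to_kv(hdr, h$scan)
  write_kv(hdr, "orig_samples", h$orig_samples)
  write_kv(hdr, "reduced_samples", h$reduced_samples)
  write_kv(hdr, "dtype", h$dtype)
  write_kv(hdr, "bytes_per_pixel", h$bytes_per_pixel)
  write_kv(hdr, "rows_dropped", h$drops$rows)
  write_kv(hdr, "cols_dropped", h$drops$cols)
  write_kv(hdr, "frames_dropped", h$drops$frames)
  write_kv(hdr, "clip_count", h$clip_count)
  write_kv(hdr, "n_blobs", length(cstack$blobs))
  writeLines("BINARY", hdr)
  close(hdr)
  writeChar(paste0(paste(hdrtxt, collapse = "\n"), "\n"), con, eos = NULL)
  write_section(con, cstack$mask_payload)
  hcomp <- cstack$codec_variant_id == hcomp_variant_id
  for (b in cstack$blobs) {
    if (hcomp) {
      meta <- as.integer(c(b$scale, b$n_levels, b$original_shape))
      writeBin(meta, con, size = 4L, endian = "little")
      write_section(con, b$payload)
    } else write_section(con, b)
  }
  invisible(path)
}

#' @rdname write_mxz
#' @export
read_mxz <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "MXZ 1")) stop("not an MXZ container: ", path)
  kv <- read_kv_block(con, "BINARY")
  getc <- function(key) trimws(kv[[key]])
  header <- list(
    format_version = 1L,
    pipeline = getc("pipeline"),
    orig_geometry = kv_geometry(kv, "orig_"), orig_scan = kv_scan(kv, "orig_"),
    geometry = kv_geometry(kv), scan = kv_scan(kv),
    orig_samples = kv_get(kv, "orig_samples"),
    reduced_samples = kv_get(kv, "reduced_samples"),
    dtype = getc("dtype"),
    bytes_per_pixel = as.integer(kv_get(kv, "bytes_per_pixel")),
    drops = list(rows = as.integer(kv_get(kv, "rows_dropped")),
                 cols = as.integer(kv_get(kv, "cols_dropped")),
                 frames = as.integer(kv_get(kv, "frames_dropped"))),
    clip_count = as.integer(kv_get(kv, "clip_count")))
  variant <- getc("codec_variant_id")
  n_blobs <- as.integer(kv_get(kv, "n_blobs"))
  mask_payload <- read_section(con)
  hcomp <- variant == hcomp_variant_id
  blobs <- vector("list", n_blobs)
  for (i in seq_len(n_blobs)) {
    if (hcomp) {
      meta <- readBin(con, "integer", n = 4L, size = 4L, endian = "little")
      blobs[[i]] <- structure(
        list(scale = meta[1], payload = read_section(con),
             n_levels = meta[2], original_shape = meta[3:4],
             codec_variant_id = variant),
        class = "hcomp_blob")
    } else blobs[[i]] <- read_section(con)
  }
  structure(list(header = header, mask_payload = mask_payload,
                 blobs = blobs, codec_variant_id = variant),
            class = "mx_compressed")
}
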