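# Frame model and format decoding.
#
# A frame is a grayscale intensity matrix in [0, 1] plus its acquisition time
# in seconds post-injection. Intensities are normalised by the container's
# bit depth at decode time so that all downstream math is device-independent.

FUNDUS_DIALECTS <- c("spectralis", "topcon", "fundus")

#' Construct a frame
#'
#' @param pixels Numeric matrix with finite values in `[0, 1]`, at least
#'   64 x 64.
#' @param t_acq Seconds post-injection (`NA` if not yet recovered).
#' @param source_path Provenance of the frame.
#' @param dialect Hardware dialect tag (e.g. `"spectralis"`, `"topcon"`,
#'   `"generic"`). Fundus dialects prefer the green channel when reducing
#'   colour input (fluorescein emission peaks near 520 nm).
#' @param meta Optional named list of decoder metadata (e.g. embedded time).
#' @return An object of class `ffa_frame`.
#' @export
new_frame <- function(pixels, t_acq = NA_real_, source_path = NA_character_,
                      dialect = "generic", meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.", class = "ffa_parameter_error")
  }
  if (nrow(pixels) < 64 || ncol(pixels) < 64) {
    abort(sprintf("Frame must be at least 64x64 (got %dx%d).",
                  nrow(pixels), ncol(pixels)),
          class = "ffa_parameter_error")
  }
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 1) {
    abort("Frame pixels must be finite and lie in [0, 1].",
          class = "ffa_parameter_error")
  }
  if (!is.na(t_acq) && t_acq < 0) {
    abort("`t_acq` must be non-negative.", class = "ffa_parameter_error")
  }
  structure(
    list(pixels = pixels, t_acq = as.numeric(t_acq),
         source_path = source_path, dialect = dialect, meta = meta),
    class = "ffa_frame"
  )
}

#' @export
print.ffa_frame <- function(x, ...) {
  cat(sprintf("<ffa_frame %dx%d t=%ss dialect=%s>\n",
              nrow(x$pixels), ncol(x$pixels),
              ifelse(is.na(x$t_acq), "?", format(x$t_acq)), x$dialect))
  invisible(x)
}

#' Reduce a decoded array to grayscale luminance
#'
#' Fundus dialects keep the green channel (fluorescein emission); other
#' dialects average the channels.
#' @noRd
to_luminance <- function(arr, dialect) {
  if (length(dim(arr)) == 2) return(arr)
  nch <- dim(arr)[3]
  if (nch >= 3 && tolower(dialect) %in% FUNDUS_DIALECTS) {
    return(arr[, , 2])
  }
  apply(arr[, , seq_len(min(nch, 3)), drop = FALSE], c(1, 2), mean)
}

#' Read one FFA frame from disk
#'
#' Decodes TIFF, PNG, JPEG, BMP or DICOM into an [new_frame()] with pixels
#' normalised to `[0, 1]` by the container's bit depth. Multi-channel input is
#' reduced to luminance (green channel for fundus dialects). Embedded time
#' metadata (TIFF description tag `t_acq=<s>`, DICOM `AcquisitionTime`) is
#' captured into the frame's `meta` but not interpreted here; see
#' [recover_time()].
#'
#' @param path Image file path.
#' @param dialect Hardware dialect tag.
#' @return An `ffa_frame`.
#' @export
read_frame <- function(path, dialect = "generic") {
  if (!file.exists(path)) {
    abort(sprintf("Image file does not exist: %s", path), class = "ffa_decode_error")
  }
  ext <- tolower(tools::file_ext(path))
  meta <- list()
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = {
        img <- tiff::readTIFF(path, info = TRUE)
        desc <- attr(img, "description")
        if (!is.null(desc)) meta$description <- desc
        img
      },
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      bmp = read_bmp(path),
      dcm = {
        d <- read_dicom(path)
        meta$acquisition_time <- d$acquisition_time
        d$pixels
      },
      abort(sprintf("Unsupported image format '.%s' for %s", ext, path),
            class = "ffa_format_error")
    ),
    error = function(e) {
      if (inherits(e, "ffa_format_error")) stop(e)
      abort(sprintf("Failed to decode %s: %s", path, conditionMessage(e)),
            class = "ffa_decode_error")
    }
  )
  px <- to_luminance(arr, dialect)
  px <- clamp(px, 0, 1)    # guard against >1 from lossy JPEG round-off
  attributes(px) <- list(dim = dim(px))   # drop decoder tag attributes
  # time embedded in TIFF description as "t_acq=<seconds>"
  if (!is.null(meta$description)) {
    m <- regmatches(meta$description,
                    regexec("t_acq=([0-9.]+)", meta$description))[[1]]
    if (length(m) == 2) meta$t_acq <- as.numeric(m[2])
  }
  new_frame(px, t_acq = NA_real_, source_path = path, dialect = dialect,
            meta = meta)
}

#' Write a frame to disk (PNG or 16-bit TIFF)
#'
#' A 16-bit TIFF decode/renormalise round trip preserves pixels to 1/65535.
#' Acquisition time is not embedded (the installed TIFF writer exposes no
#' text tags); pair the frames with a sidecar timing table or timed
#' filenames instead.
#'
#' @param frame `ffa_frame`.
#' @param path Destination; extension selects the container.
#' @export
write_frame <- function(frame, path) {
  ext <- tolower(tools::file_ext(path))
  px <- clamp(frame$pixels)
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L,
                           compression = "none"),
    abort(sprintf("Unsupported output format '.%s'", ext), class = "ffa_format_error")
  )
  invisible(path)
}

# ---- minimal BMP codec (uncompressed 8-bit palette / 24-bit) -----------------
# No installed R package reads BMP; this covers the uncompressed Windows
# BITMAPINFOHEADER variants that fundus exports use.

read_bmp <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM") {
    stop("not a BMP file")
  }
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * 256^(0:1))
  data_off <- u32(10)
  width <- u32(18); height <- u32(22)
  bpp <- u16(28); compression <- u32(30)
  if (compression != 0) stop("compressed BMP not supported")
  if (!(bpp %in% c(8L, 24L))) stop(sprintf("unsupported BMP depth %d", bpp))
  row_bytes <- ((width * bpp / 8 + 3) %/% 4) * 4
  out <- matrix(0, height, width)
  if (bpp == 8L) {
    # grayscale palette assumed (index == intensity)
    for (r in seq_len(height)) {
      off <- data_off + (r - 1) * row_bytes
      v <- as.integer(raw[off + 1:width])
      out[height - r + 1, ] <- v / 255
    }
  } else {
    for (r in seq_len(height)) {
      off <- data_off + (r - 1) * row_bytes
      v <- as.integer(raw[off + 1:(3 * width)])
      b <- v[seq(1, 3 * width, 3)]; g <- v[seq(2, 3 * width, 3)]
      rr <- v[seq(3, 3 * width, 3)]
      out[height - r + 1, ] <- (rr + g + b) / (3 * 255)
    }
    dim(out) <- c(height, width)
  }
  out
}

#' @noRd
write_bmp <- function(pixels, path) {
  # 8-bit grayscale-palette BMP, rows bottom-up, 4-byte aligned
  h <- nrow(pixels); w <- ncol(pixels)
  row_bytes <- ((w + 3) %/% 4) * 4
  data_off <- 54 + 256 * 4
  file_size <- data_off + row_bytes * h
  u32 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256, x %/% 16777216 %% 256))
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256))
  header <- c(charToRaw("BM"), u32(file_size), u32(0), u32(data_off),
              u32(40), u32(w), u32(h), u16(1), u16(8), u32(0), u32(row_bytes * h),
              u32(2835), u32(2835), u32(256), u32(0))
  palette <- as.raw(as.vector(rbind(0:255, 0:255, 0:255, rep(0, 256))))
  body <- raw(row_bytes * h)
  q <- round(clamp(pixels) * 255)
  for (r in seq_len(h)) {
    off <- (r - 1) * row_bytes
    body[off + 1:w] <- as.raw(q[h - r + 1, ])
  }
  writeBin(c(header, palette, body), path)
  invisible(path)
}

# ---- minimal DICOM codec (explicit VR little endian, monochrome) -------------
# oro.dicom is not available; this reads the uncompressed monochrome subset
# sufficient for FFA exports: Rows, Columns, BitsAllocated, AcquisitionTime,
# PixelData. The companion writer emits synthetic test files only.

read_dicom <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic)")
  }
  pos <- 133L  # after 128-byte preamble + "DICM"
  u16 <- function(off) sum(as.integer(raw[off + 0:1]) * 256^(0:1))
  u32 <- function(off) sum(as.integer(raw[off + 0:3]) * 256^(0:3))
  rows <- cols <- bits <- NA_integer_
  acq_time <- NA_character_
  pixel_raw <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8 <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2)
    vr <- rawToChar(raw[pos + 4:5])
    if (grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% long_vrs) {
        len <- u32(pos + 8); data_start <- pos + 12
      } else {
        len <- u16(pos + 6); data_start <- pos + 8
      }
    } else {
      # implicit VR
      len <- u32(pos + 4); data_start <- pos + 8
    }
    val_raw <- raw[data_start + seq_len(len) - 1]
    tag <- sprintf("%04x%04x", group, elem)
    if (tag == "00080032") acq_time <- trimws(rawToChar(val_raw))
    if (tag == "00280010") rows <- u16(data_start)
    if (tag == "00280011") cols <- u16(data_start)
    if (tag == "00280100") bits <- u16(data_start)
    if (tag == "7fe00010") { pixel_raw <- val_raw; break }
    pos <- data_start + len
  }
  if (is.null(pixel_raw) || is.na(rows) || is.na(cols)) {
    stop("incomplete DICOM: missing pixel data or dimensions")
  }
  if (is.na(bits)) bits <- 8L
  if (bits == 8L) {
    v <- as.integer(pixel_raw) / 255
  } else {
    n <- length(pixel_raw) %/% 2
    v <- (as.integer(pixel_raw[seq(1, 2 * n, 2)]) +
            256 * as.integer(pixel_raw[seq(2, 2 * n, 2)])) / 65535
  }
  list(pixels = matrix(v[seq_len(rows * cols)], rows, cols, byrow = TRUE),
       acquisition_time = acq_time)
}

#' Write a minimal synthetic DICOM file (test fixture generator)
#'
#' Explicit VR little endian, 8-bit monochrome, with `AcquisitionTime` in
#' `HHMMSS` form. Intended only to exercise the decoder on synthetic data.
#' @noRd
write_dicom <- function(pixels, path, acquisition_time = NULL) {
  h <- nrow(pixels); w <- ncol(pixels)
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
  u32 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256, x %/% 16777216 %% 256))
  elem_short <- function(group, el, vr, data) {
    if (length(data) %% 2 == 1) data <- c(data, as.raw(if (vr %in% c("TM","CS")) 0x20 else 0x00))
    c(u16(group), u16(el), charToRaw(vr), u16(length(data)), data)
  }
  elem_long <- function(group, el, vr, data) {
    c(u16(group), u16(el), charToRaw(vr), as.raw(c(0, 0)), u32(length(data)), data)
  }
  body <- c(
    elem_short(0x0008, 0x0016, "UI", charToRaw("1.2.840.10008.5.1.4.1.1.7")),
    if (!is.null(acquisition_time))
      elem_short(0x0008, 0x0032, "TM", charToRaw(acquisition_time)),
    elem_short(0x0028, 0x0010, "US", u16(h)),
    elem_short(0x0028, 0x0011, "US", u16(w)),
    elem_short(0x0028, 0x0100, "US", u16(8)),
    elem_long(0x7fe0, 0x0010, "OB", as.raw(round(clamp(t(pixels)) * 255)))
  )
  writeBin(c(raw(128), charToRaw("DICM"), body), path)
  invisible(path)
}
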