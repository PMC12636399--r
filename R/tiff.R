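# Minimal baseline TIFF support for single-plane grayscale images.
#
# No TIFF package ships with this R stack, so the few fields needed for
# uncompressed single-strip grayscale are implemented here directly:
# little-endian, 32-bit float (write) and 8/16-bit unsigned or 32-bit
# float (read), compression "none". This intentionally covers only the
# images this pipeline produces and consumes.

tiff_tag <- function(id, type, count, value_raw) {
  # value_raw must be exactly 4 bytes (value or offset)
  c(writeBin(as.integer(id), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value_raw)
}

le4 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
le2pad <- function(x) c(writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little"), as.raw(c(0, 0)))

#' Write an intensity image as TIFF
#'
#' Single-plane grayscale 32-bit float, uncompressed, little-endian
#' baseline TIFF (readable by ImageJ, tifffile, scikit-image, ...).
#'
#' @param img an [intensity_image()] or plain numeric matrix.
#' @param path output file.
#' @export
write_intensity_tiff <- function(img, path) {
  mat <- unclass(img)
  h <- nrow(mat); w <- ncol(mat)
  # TIFF is row-major top-to-bottom; our matrix rows are already y
  pix <- as.numeric(t(mat))
  data_offset <- 8L
  nbytes <- 4L * w * h
  ifd_offset <- data_offset + nbytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")
  stopifnot(seek(con) == data_offset)
  writeBin(pix, con, size = 4, endian = "little")

  tags <- list(
    tiff_tag(256, 3, 1, le2pad(w)),          # ImageWidth
    tiff_tag(257, 3, 1, le2pad(h)),          # ImageLength
    tiff_tag(258, 3, 1, le2pad(32)),         # BitsPerSample
    tiff_tag(259, 3, 1, le2pad(1)),          # Compression: none
    tiff_tag(262, 3, 1, le2pad(1)),          # Photometric: BlackIsZero
    tiff_tag(273, 4, 1, le4(data_offset)),   # StripOffsets
    tiff_tag(277, 3, 1, le2pad(1)),          # SamplesPerPixel
    tiff_tag(278, 3, 1, le2pad(h)),          # RowsPerStrip
    tiff_tag(279, 4, 1, le4(nbytes)),        # StripByteCounts
    tiff_tag(339, 3, 1, le2pad(3))           # SampleFormat: IEEE float
  )
  writeBin(as.integer(length(tags)), con, size = 2, endian = "little")
  for (tg in tags) writeBin(tg, con)
  writeBin(as.integer(0), con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

#' Read a grayscale TIFF into an intensity image
#'
#' Supports uncompressed single-plane grayscale baseline TIFF (either
#' byte order; 8/16-bit unsigned or 32-bit float), which covers the
#' files written by [write_intensity_tiff()] and typical exported
#' reconstruction images. Integer data are rescaled to `[0, 1]` by the
#' type maximum.
#'
#' @param path TIFF file.
#' @param pixel_size_nm pixel pitch to attach (nm).
#' @param channel channel label to attach.
#' @return An [intensity_image()].
#' @export
read_intensity_tiff <- function(path, pixel_size_nm = NA_real_,
                                channel = "ch561") {
  con <- file(path, "rb")
  on.exit(close(con))
  order_mark <- rawToChar(readBin(con, raw(), 2))
  endian <- switch(order_mark, II = "little", MM = "big",
                   stopf("not a TIFF file: %s", path))
  magic <- readBin(con, integer(), 1, size = 2, endian = endian)
  if (magic != 42) stopf("not a TIFF file: %s", path)
  ifd <- readBin(con, integer(), 1, size = 4, endian = endian)
  seek(con, ifd)
  ntag <- readBin(con, integer(), 1, size = 2, endian = endian)
  tags <- list()
  for (i in seq_len(ntag)) {
    id <- readBin(con, integer(), 1, size = 2, endian = endian,
                  signed = FALSE)
    type <- readBin(con, integer(), 1, size = 2, endian = endian)
    count <- readBin(con, integer(), 1, size = 4, endian = endian)
    vraw <- readBin(con, raw(), 4)
    val <- if (type == 3) {
      readBin(vraw[1:2], integer(), 1, size = 2, endian = endian,
              signed = FALSE)
    } else {
      readBin(vraw, integer(), 1, size = 4, endian = endian)
    }
    tags[[as.character(id)]] <- list(type = type, count = count, value = val)
  }
  g <- function(id, default = NULL) {
    t <- tags[[as.character(id)]]
    if (is.null(t)) default else t$value
  }
  w <- g(256); h <- g(257)
  bits <- g(258, 1L); comp <- g(259, 1L); fmt <- g(339, 1L)
  if (is.null(w) || is.null(h)) stopf("TIFF missing dimensions: %s", path)
  if (comp != 1) stopf("only uncompressed TIFF is supported (%s)", path)
  offset <- g(273); nbytes <- g(279, (bits / 8) * w * h)
  seek(con, offset)
  n <- w * h
  vals <- if (fmt == 3 && bits == 32) {
    readBin(con, numeric(), n, size = 4, endian = endian)
  } else if (fmt %in% c(1, 4) && bits == 8) {
    readBin(con, integer(), n, size = 1, endian = endian,
            signed = FALSE) / 255
  } else if (fmt %in% c(1, 4) && bits == 16) {
    readBin(con, integer(), n, size = 2, endian = endian,
            signed = FALSE) / 65535
  } else {
    stopf("unsupported TIFF sample format (bits=%d, format=%d)", bits, fmt)
  }
  mat <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  intensity_image(mat, pixel_size_nm = pixel_size_nm, channel = channel)
}
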