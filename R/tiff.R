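# Minimal baseline TIFF support.
#
# Scope: uncompressed (Compression = 1), chunky (PlanarConfiguration = 1),
# 8- or 16-bit unsigned samples, grayscale or RGB(A), single image (first
# IFD).  This covers flatbed transmission scans of radiochromic film; no
# general TIFF package is available in this stack, so the small subset is
# parsed directly.

read_tiff_image <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file (too short): ", path)
  byte_order <- rawToChar(raw[1:2])
  endian <- switch(byte_order, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                               size = 2, signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer",
                               size = 4, endian = endian)
  if (u16(2L) != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd <- u32(4L)
  n_entries <- u16(ifd)
  tags <- list()
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)
  for (k in seq_len(n_entries)) {
    e <- ifd + 2L + (k - 1L) * 12L
    tag <- u16(e); type <- u16(e + 2L); count <- u32(e + 4L)
    sz <- type_size[[as.character(type)]] %||% 1L
    off <- if (sz * count <= 4L) e + 8L else u32(e + 8L)
    vals <- switch(as.character(type),
      `3` = vapply(seq_len(count) - 1L, function(i) u16(off + 2L * i), 0L),
      `4` = vapply(seq_len(count) - 1L, function(i) u32(off + 4L * i), 0L),
      `1` = as.integer(raw[(off + 1L):(off + count)]),
      NULL)
    tags[[as.character(tag)]] <- vals
  }
  g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
  width <- g(256); height <- g(257)
  if (is.null(width) || is.null(height)) stop("TIFF missing dimensions")
  bits <- g(258, 8L)
  if (length(unique(bits)) != 1L || !unique(bits) %in% c(8L, 16L))
    stop("unsupported TIFF bit depth: ", paste(bits, collapse = "/"))
  bits <- bits[1L]
  if (g(259, 1L) != 1L) stop("compressed TIFF not supported")
  if (g(284, 1L) != 1L) stop("planar TIFF not supported")
  spp <- g(277, 1L)
  offsets <- g(273); counts <- g(279)
  if (is.null(offsets)) stop("TIFF missing strip offsets")
  rows_per_strip <- g(278, height)
  payload <- raw(0)
  for (k in seq_along(offsets)) {
    nb <- if (!is.null(counts)) counts[k]
          else width * min(rows_per_strip, height) * spp * (bits / 8L)
    payload <- c(payload, raw[(offsets[k] + 1L):(offsets[k] + nb)])
  }
  vals <- readBin(payload, "integer", n = width * height * spp,
                  size = bits / 8L, signed = FALSE, endian = endian)
  # stored row-major, samples interleaved -> array [height, width, spp]
  arr <- aperm(array(vals, dim = c(spp, width, height)), c(3L, 2L, 1L))
  storage.mode(arr) <- "double"
  arr
}

# test/tooling helper: write an uncompressed 8-bit TIFF (grayscale or RGB),
# little-endian, single strip
write_tiff_image <- function(img, path) {
  if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
  h <- dim(img)[1L]; w <- dim(img)[2L]; spp <- dim(img)[3L]
  stopifnot(spp %in% c(1L, 3L), all(img >= 0), all(img <= 255))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    u16(tag); u16(type); u32(count); u32(value)
  }
  n_tags <- 9L
  ifd_off <- 8L
  bps_off <- ifd_off + 2L + n_tags * 12L + 4L   # BitsPerSample array (RGB)
  data_off <- bps_off + (if (spp == 3L) 6L else 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL); u16(42L); u32(ifd_off)
  u16(n_tags)
  entry(256, 3, 1, w)                       # ImageWidth
  entry(257, 3, 1, h)                       # ImageLength
  if (spp == 3L) entry(258, 3, 3, bps_off) else entry(258, 3, 1, 8)
  entry(259, 3, 1, 1)                       # Compression = none
  entry(262, 3, 1, if (spp == 3L) 2 else 1) # Photometric
  entry(273, 4, 1, data_off)                # StripOffsets
  entry(277, 3, 1, spp)                     # SamplesPerPixel
  entry(278, 3, 1, h)                       # RowsPerStrip
  entry(279, 4, 1, w * h * spp)             # StripByteCounts
  u32(0L)                                   # next IFD
  if (spp == 3L) { u16(8L); u16(8L); u16(8L) }
  # interleave samples, row-major
  px <- aperm(img, c(3L, 2L, 1L))
  writeBin(as.raw(as.integer(round(px))), con)
  invisible(path)
}
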