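# Minimal baseline TIFF codec for dynamic grayscale stacks.
#
# The package needs multi-page grayscale TIFF (the exchange format of the
# acquisition systems it targets) but depends only on base R, so a small
# baseline codec lives here: uncompressed, 1 sample/pixel, 8- or 16-bit
# unsigned, one or more strips per page. Writing is little-endian; reading
# handles both byte orders. Anything fancier (compression, RGB, tiles,
# planar configs) is rejected with a classed error rather than guessed at.

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

tiff_entry <- function(tag, type, count, value_raw4) {
  c(u16le(tag), u16le(type), u32le(count), value_raw4)
}
short_val <- function(x) c(u16le(x), as.raw(c(0, 0)))

#' Write a grayscale image stack as multi-page TIFF
#'
#' Baseline TIFF: uncompressed, single channel, 8- or 16-bit unsigned,
#' little-endian, one strip per page. Pixel values must already be integers
#' within the bit-depth range.
#'
#' @param frames integer array `T x H x W`.
#' @param path output file.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @seealso [read_tiff_stack()]
#' @export
write_tiff_stack <- function(frames, path, bit_depth = 8) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (!bit_depth %in% c(8, 16))
    pq_stop("write_tiff_stack supports bit_depth 8 or 16", "pq_invalid_input")
  maxv <- 2^bit_depth - 1
  if (min(frames) < 0 || max(frames) > maxv)
    pq_stop("pixel values outside the bit-depth range", "pq_invalid_input")
  d <- dim(frames); n_t <- d[1L]; h <- d[2L]; w <- d[3L]
  bpp <- bit_depth / 8
  strip_bytes <- h * w * bpp
  n_tags <- 10L
  ifd_bytes <- 2L + n_tags * 12L + 4L
  # layout: 8-byte header, then per page [pixel data][IFD]
  page_bytes <- strip_bytes + ifd_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49)), u16le(42L), u32le(8L + strip_bytes)), con)
  for (t in seq_len(n_t)) {
    page_off <- 8L + (t - 1L) * page_bytes
    vals <- as.vector(t(frames[t, , , drop = TRUE]))  # row-major
    if (bpp == 1) writeBin(as.raw(vals), con)
    else writeBin(writeBin(as.integer(vals), raw(), size = 2L, endian = "little"), con)
    next_ifd <- if (t < n_t) page_off + page_bytes + strip_bytes else 0L
    ifd <- c(
      u16le(n_tags),
      tiff_entry(256L, 4L, 1L, u32le(w)),             # ImageWidth
      tiff_entry(257L, 4L, 1L, u32le(h)),             # ImageLength
      tiff_entry(258L, 3L, 1L, short_val(bit_depth)), # BitsPerSample
      tiff_entry(259L, 3L, 1L, short_val(1L)),        # Compression: none
      tiff_entry(262L, 3L, 1L, short_val(1L)),        # Photometric: BlackIsZero
      tiff_entry(273L, 4L, 1L, u32le(page_off)),      # StripOffsets
      tiff_entry(277L, 3L, 1L, short_val(1L)),        # SamplesPerPixel
      tiff_entry(278L, 4L, 1L, u32le(h)),             # RowsPerStrip
      tiff_entry(279L, 4L, 1L, u32le(strip_bytes)),   # StripByteCounts
      tiff_entry(339L, 3L, 1L, short_val(1L)),        # SampleFormat: uint
      u32le(next_ifd)
    )
    writeBin(ifd, con)
  }
  invisible(path)
}

# --- reader ----------------------------------------------------------------

tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)

read_tiff_values <- function(raw, entry_off, endian) {
  # entry_off is the 0-based offset of the 12-byte IFD entry
  type <- readBin(raw[(entry_off + 3L):(entry_off + 4L)], "integer",
                  size = 2L, signed = FALSE, endian = endian)
  count <- readBin(raw[(entry_off + 5L):(entry_off + 8L)], "integer",
                   size = 4L, endian = endian)
  size <- tiff_type_size[as.character(type)]
  if (is.na(size)) return(NULL)  # field type we never need (RATIONAL, ASCII...)
  nbytes <- size * count
  data_off <- if (nbytes <= 4L) entry_off + 8L else
    readBin(raw[(entry_off + 8L):(entry_off + 11L)], "integer",
            size = 4L, endian = endian)
  bytes <- raw[(data_off + 1L):(data_off + nbytes)]
  if (size == 1L) as.integer(bytes)
  else readBin(bytes, "integer", n = count, size = size,
               signed = size == 4L, endian = endian)
}

read_tiff_page <- function(raw, ifd_off, endian) {
  n <- readBin(raw[(ifd_off + 1L):(ifd_off + 2L)], "integer",
               size = 2L, signed = FALSE, endian = endian)
  tags <- integer(n); entry_offs <- integer(n)
  fields <- list()
  for (i in seq_len(n)) {
    eo <- ifd_off + 2L + (i - 1L) * 12L
    tag <- readBin(raw[(eo + 1L):(eo + 2L)], "integer", size = 2L,
                   signed = FALSE, endian = endian)
    fields[[as.character(tag)]] <- read_tiff_values(raw, eo, endian)
  }
  next_off <- readBin(raw[(ifd_off + 2L + n * 12L + 1L):(ifd_off + 2L + n * 12L + 4L)],
                      "integer", size = 4L, endian = endian)
  g <- function(tag, default = NULL) fields[[as.character(tag)]] %||% default
  w <- g(256L); h <- g(257L)
  if (is.null(w) || is.null(h))
    pq_stop("TIFF page missing image dimensions", "pq_unsupported_format")
  if (g(259L, 1L) != 1L)
    pq_stop("compressed TIFF is not supported", "pq_unsupported_format")
  spp <- g(277L, 1L)
  if (spp != 1L || g(262L, 1L) == 2L)
    pq_stop("multi-channel/RGB TIFF is not supported; expected single-channel grayscale",
            "pq_unsupported_format")
  bits <- g(258L, 1L)
  if (!bits %in% c(8L, 16L))
    pq_stop(sprintf("unsupported bits per sample: %d (need 8 or 16)", bits),
            "pq_unsupported_format")
  if (g(339L, 1L) != 1L)
    pq_stop("only unsigned-integer TIFF samples are supported", "pq_unsupported_format")
  offs <- g(273L); counts <- g(279L)
  if (is.null(offs) || is.null(counts))
    pq_stop("TIFF page missing strip layout", "pq_unsupported_format")
  vals <- integer(0)
  bpp <- bits / 8L
  for (i in seq_along(offs)) {
    bytes <- raw[(offs[i] + 1L):(offs[i] + counts[i])]
    vals <- c(vals, if (bpp == 1L) as.integer(bytes)
              else readBin(bytes, "integer", n = counts[i] / 2L, size = 2L,
                           signed = FALSE, endian = endian))
  }
  if (length(vals) != w * h)
    pq_stop("TIFF strip data does not match page dimensions", "pq_unsupported_format")
  list(pixels = matrix(vals, nrow = h, ncol = w, byrow = TRUE),
       bits = bits, next_off = next_off)
}

#' Read a multi-page grayscale TIFF stack
#'
#' Supports baseline uncompressed single-channel TIFF, 8- or 16-bit
#' unsigned, either byte order. RGB/multi-channel or compressed input is
#' rejected with an `pq_unsupported_format` error.
#'
#' @param path TIFF file.
#' @return list with `frames` (integer array `T x H x W`) and `bit_depth`.
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) pq_stop("not a TIFF file (too short)", "pq_unsupported_format")
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   pq_stop("not a TIFF file (bad byte-order mark)",
                           "pq_unsupported_format"))
  if (readBin(raw[3:4], "integer", size = 2L, signed = FALSE, endian = endian) != 42L)
    pq_stop("not a TIFF file (bad magic)", "pq_unsupported_format")
  ifd_off <- readBin(raw[5:8], "integer", size = 4L, endian = endian)
  pages <- list(); bits <- NULL
  while (ifd_off != 0L) {
    pg <- read_tiff_page(raw, ifd_off, endian)
    if (is.null(bits)) bits <- pg$bits
    else if (bits != pg$bits)
      pq_stop("mixed bit depths across TIFF pages", "pq_unsupported_format")
    pages[[length(pages) + 1L]] <- pg$pixels
    ifd_off <- pg$next_off
  }
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  frames <- array(0L, dim = c(length(pages), h, w))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]]
  list(frames = frames, bit_depth = bits)
}
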