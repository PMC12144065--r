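#' Minimal multi-page TIFF I/O for grayscale stacks
#'
#' Reads and writes uncompressed, little-endian, single-channel baseline
#' TIFF files with 8- or 16-bit unsigned samples, one page per time point.
#' This covers the stacks produced by [simulate_vacuole_sequence()] and the
#' common export path of scientific imaging tools (ImageJ "save as TIFF",
#' `tifffile.imwrite` with default settings). Compressed, tiled, planar or
#' big-endian files are rejected with an informative error.
#'
#' @param frames numeric array `H x W x T` (or `H x W` for a single page)
#'   of nonnegative intensities.
#' @param path file path.
#' @param bits bits per sample, 8 or 16. Intensities are rounded and
#'   clipped to the corresponding unsigned range.
#' @return `write_tiff_stack()` returns `path` invisibly;
#'   `read_tiff_stack()` returns a numeric array `H x W x T`.
#' @keywords internal
#' @export
write_tiff_stack <- function(frames, path, bits = 8L) {
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  stopifnot(length(dim(frames)) == 3L, bits %in% c(8L, 16L))
  H <- dim(frames)[1]; W <- dim(frames)[2]; TT <- dim(frames)[3]
  if (H < 1 || W < 1) stop("frame dimensions must be positive")
  maxval <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))

  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  # fixed-size IFD: 9 entries -> 2 + 9*12 + 4 bytes
  ifd_size <- 2 + 9 * 12 + 4
  page_bytes <- H * W * (bits / 8)
  # layout: header | [IFD_1 | data_1] | [IFD_2 | data_2] | ...
  ifd_off <- 8 + (seq_len(TT) - 1) * (ifd_size + page_bytes)
  dat_off <- ifd_off + ifd_size

  writeBin(charToRaw("II"), con)
  w16(42); w32(ifd_off[1])

  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3) { w16(value); w16(0) } else w32(value)
  }
  for (p in seq_len(TT)) {
    w16(9)                                   # entry count
    entry(256, 3, 1, W)                      # ImageWidth
    entry(257, 3, 1, H)                      # ImageLength
    entry(258, 3, 1, bits)                   # BitsPerSample
    entry(259, 3, 1, 1)                      # Compression: none
    entry(262, 3, 1, 1)                      # Photometric: BlackIsZero
    entry(273, 4, 1, dat_off[p])             # StripOffsets
    entry(277, 3, 1, 1)                      # SamplesPerPixel
    entry(278, 3, 1, H)                      # RowsPerStrip
    entry(279, 4, 1, page_bytes)             # StripByteCounts
    w32(if (p < TT) ifd_off[p + 1] else 0)   # next IFD
    px <- t(frames[, , p])                   # row-major pixel order
    px <- pmin(pmax(round(px), 0), maxval)
    writeBin(as.integer(px), con, size = bits / 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  if (!identical(rawToChar(raw[1:2]), "II"))
    stop("only little-endian ('II') TIFF is supported")
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (u16(2) != 42) stop("not a TIFF file: ", path)

  read_vals <- function(type, count, off) {
    # type 3 = SHORT (2 bytes), type 4 = LONG (4 bytes)
    sz <- if (type == 3) 2 else 4
    base <- if (count * sz <= 4) off + 8 else u32(off + 8)
    vapply(seq_len(count) - 1L, function(k) {
      if (type == 3) u16(base + k * 2) else u32(base + k * 4)
    }, numeric(1))
  }

  pages <- list(); ifd <- u32(4)
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n) - 1L) {
      off <- ifd + 2 + e * 12
      tag <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      if (type %in% c(3, 4)) tags[[as.character(tag)]] <- read_vals(type, count, off)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    W <- g(256); H <- g(257)
    bits <- g(258, 8); comp <- g(259, 1); spp <- g(277, 1)
    if (is.null(W) || is.null(H)) stop("TIFF page missing dimensions")
    if (comp != 1) stop("compressed TIFF not supported (compression=", comp, ")")
    if (spp != 1) stop("only single-channel TIFF supported")
    if (!bits[1] %in% c(8, 16)) stop("only 8/16-bit TIFF supported")
    offs <- g(273); cnts <- g(279)
    dat <- unlist(lapply(seq_along(offs), function(k) {
      readBin(raw[offs[k] + seq_len(cnts[k])], "integer",
              n = cnts[k] / (bits[1] / 8), size = bits[1] / 8,
              endian = "little", signed = FALSE)
    }))
    if (length(dat) != H * W) stop("TIFF strip data does not match dimensions")
    pages[[length(pages) + 1L]] <- t(matrix(dat, nrow = W, ncol = H))
    ifd <- u32(ifd + 2 + n * 12)
  }
  if (!length(pages)) stop("TIFF contains no pages")
  array(unlist(pages), dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
}
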