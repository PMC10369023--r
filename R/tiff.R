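# Minimal baseline TIFF codec.
#
# No TIFF package exists in this R stack, so the package carries its own
# reader/writer for the narrow slice of TIFF 6.0 that cone-catch stacks
# need: uncompressed single-sample (grayscale) pages, 32-bit float or
# 8/16-bit unsigned, one page per channel, either byte order on read
# (always little-endian on write). Anything fancier (compression, tiles,
# palette, RGB pages) is rejected with a clear error.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, samples = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

#' Write a multi-page float TIFF
#'
#' Writes a numeric `H x W x C` array as an uncompressed little-endian TIFF
#' with one 32-bit-float grayscale page (IFD) per channel. This is the
#' on-disk form of a cone-catch stack; readable by any scientific TIFF
#' reader.
#'
#' @param x numeric matrix or `H x W x C` array.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_tiff()]
#' @export
write_tiff <- function(x, path) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  h <- dim(x)[1]; w <- dim(x)[2]; npages <- dim(x)[3]
  page_bytes <- h * w * 4L
  data_off <- 8L + page_bytes * (seq_len(npages) - 1L)
  ifd_size <- 2L + 10L * 12L + 4L
  ifd_off <- 8L + page_bytes * npages + ifd_size * (seq_len(npages) - 1L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off[1], con, size = 4, endian = "little")
  for (p in seq_len(npages)) # pixel data, row-major
    writeBin(as.numeric(t(x[, , p])), con, size = 4, endian = "little")
  entry <- function(tag, type, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (type == 3L) { # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (p in seq_len(npages)) {
    writeBin(10L, con, size = 2, endian = "little")
    entry(TIFF_TAGS["width"], 4L, w)
    entry(TIFF_TAGS["length"], 4L, h)
    entry(TIFF_TAGS["bits"], 3L, 32L)
    entry(TIFF_TAGS["compression"], 3L, 1L)
    entry(TIFF_TAGS["photometric"], 3L, 1L)
    entry(TIFF_TAGS["strip_offsets"], 4L, data_off[p])
    entry(TIFF_TAGS["samples"], 3L, 1L)
    entry(TIFF_TAGS["rows_per_strip"], 4L, h)
    entry(TIFF_TAGS["strip_bytes"], 4L, page_bytes)
    entry(TIFF_TAGS["sample_format"], 3L, 3L)
    next_off <- if (p < npages) ifd_off[p + 1L] else 0L
    writeBin(next_off, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Reads uncompressed single-sample TIFF pages (32-bit float or 8/16-bit
#' unsigned, either byte order) into an `H x W x n_pages` array. Integer
#' pages are rescaled to [0, 1] (by their type maximum) with a message, per
#' the package's linear-stack convention.
#'
#' @param path TIFF file.
#' @return numeric array `H x W x n_pages`.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("TIFF not found: ", path)
  b <- readBin(path, "raw", file.info(path)$size)
  order_tag <- rawToChar(b[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  u <- function(off, size, n = 1L) # unsigned ints, 1-based offset
    readBin(b[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = size == 4L, endian = endian)
  if (u(2L, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd_off <- u(4L, 4L)
  pages <- list()
  while (ifd_off != 0L) {
    n_ent <- u(ifd_off, 2L)
    tags <- list()
    for (e in seq_len(n_ent)) {
      eo <- ifd_off + 2L + (e - 1L) * 12L
      tag <- u(eo, 2L); type <- u(eo + 2L, 2L); count <- u(eo + 4L, 4L)
      tsize <- switch(as.character(type), `1` = 1L, `3` = 2L, `4` = 4L, NA_integer_)
      if (is.na(tsize)) next # skip rationals/ascii etc.
      vals <- if (tsize * count <= 4L) u(eo + 8L, tsize, count)
              else u(u(eo + 8L, 4L), tsize, count)
      tags[[as.character(tag)]] <- vals
    }
    gt <- function(id, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[[id]])]]
      if (is.null(v)) default else v
    }
    w <- gt("width"); h <- gt("length")
    if (is.null(w) || is.null(h)) stop("malformed TIFF IFD in ", path)
    if (gt("compression", 1L) != 1L)
      stop("compressed TIFF not supported: ", path)
    if (gt("samples", 1L) != 1L)
      stop("only single-sample (grayscale) pages supported: ", path)
    bits <- gt("bits", 1L)
    fmt <- gt("sample_format", 1L)
    offs <- gt("strip_offsets"); cnts <- gt("strip_bytes")
    if (is.null(offs) || is.null(cnts)) stop("missing strip info in ", path)
    raw_px <- do.call(c, mapply(function(o, n) b[(o + 1L):(o + n)],
                                offs, cnts, SIMPLIFY = FALSE))
    vals <- if (fmt == 3L && bits == 32L) {
      readBin(raw_px, "double", n = w * h, size = 4L, endian = endian)
    } else if (fmt %in% c(1L, 4L) && bits == 8L) {
      as.integer(readBin(raw_px, "integer", n = w * h, size = 1L,
                         signed = FALSE, endian = endian))
    } else if (fmt %in% c(1L, 4L) && bits == 16L) {
      readBin(raw_px, "integer", n = w * h, size = 2L, signed = FALSE,
              endian = endian)
    } else {
      stop(sprintf("unsupported TIFF sample layout (bits=%d, format=%d) in %s",
                   bits, fmt, path))
    }
    if (bits %in% c(8L, 16L)) {
      message(sprintf("%d-bit integer TIFF page rescaled to [0, 1]", bits))
      vals <- vals / (2^bits - 1)
    }
    pages[[length(pages) + 1L]] <- t(matrix(vals, w, h)) # row-major on disk
    ifd_off <- u(ifd_off + 2L + n_ent * 12L, 4L)
  }
  if (!length(pages)) stop("TIFF contains no pages: ", path)
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}
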