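# Minimal multi-page TIFF codec for 64-bit floating point grayscale images.
#
# Hyperspectral SRS analysis needs lossless round trips of real-valued
# (possibly negative) intensity blocks. The general-purpose TIFF bindings
# available to R cap samples at 32 bits and clamp to [0, 1], so the package
# carries its own writer/reader for the one flavour of TIFF it emits:
# classic little-endian, uncompressed, one strip per page, SampleFormat
# IEEE float, 64 bits per sample. Reading falls back to tiff::readTIFF for
# any other TIFF flavour (see read_stack).

TIFF64_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
                 photometric = 262L, strip_offsets = 273L, spp = 277L,
                 rows_per_strip = 278L, strip_bytes = 279L,
                 sample_format = 339L)

#' Low-level 64-bit float TIFF writer/reader
#'
#' Writes matrices as a multi-page grayscale TIFF with 64-bit IEEE float
#' samples (classic little-endian, uncompressed), preserving every double
#' bit-exactly. `read_tiff64` parses that flavour back into a list of
#' matrices and returns `NULL` for any other TIFF flavour so callers can
#' fall back to `tiff::readTIFF` (as [read_stack()] does).
#'
#' @param pages matrix, 3D array (pages along the third dimension) or list
#'   of matrices.
#' @param path file path.
#' @return `write_tiff64`: `path`, invisibly. `read_tiff64`: list of
#'   matrices, or `NULL`.
#' @export
write_tiff64 <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  if (is.array(pages) && length(dim(pages)) == 3L) {
    d <- dim(pages)
    pages <- lapply(seq_len(d[3]), function(k) matrix(pages[, , k],
                                                      d[1], d[2]))
  }
  if (!length(pages) || !all(vapply(pages, is.matrix, logical(1)))) {
    stop("write_tiff64 expects a matrix, 3D array or list of matrices")
  }
  total <- 8 + sum(vapply(pages, length, numeric(1))) * 8 +
    length(pages) * (2 + 10 * 12 + 4)
  if (total >= 2^31) stop("stack too large for classic TIFF (>= 2 GiB)")

  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  writeChar("II", con, nchars = 2, eos = NULL)
  u16(42L)
  data_off <- vapply(pages, length, numeric(1)) * 8
  first_ifd <- 8 + sum(data_off)
  u32(first_ifd)
  for (p in pages) {  # pixel data, row-major as TIFF requires
    writeBin(as.numeric(t(p)), con, size = 8, endian = "little")
  }
  off <- 8
  ifd_off <- first_ifd
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    entry <- function(tag, type, value) {
      u16(tag); u16(type); u32(1L)
      if (type == 3L) { u16(value); u16(0L) } else u32(value)
    }
    u16(10L)  # entry count
    entry(TIFF64_TAGS[["width"]], 4L, ncol(p))
    entry(TIFF64_TAGS[["length"]], 4L, nrow(p))
    entry(TIFF64_TAGS[["bits"]], 3L, 64L)
    entry(TIFF64_TAGS[["compression"]], 3L, 1L)
    entry(TIFF64_TAGS[["photometric"]], 3L, 1L)
    entry(TIFF64_TAGS[["strip_offsets"]], 4L, off)
    entry(TIFF64_TAGS[["spp"]], 3L, 1L)
    entry(TIFF64_TAGS[["rows_per_strip"]], 4L, nrow(p))
    entry(TIFF64_TAGS[["strip_bytes"]], 4L, length(p) * 8)
    entry(TIFF64_TAGS[["sample_format"]], 3L, 3L)
    ifd_off <- ifd_off + 2 + 10 * 12 + 4
    u32(if (i < length(pages)) ifd_off else 0L)  # next-IFD pointer
    off <- off + length(p) * 8
  }
  invisible(path)
}

#' @rdname write_tiff64
#' @export
read_tiff64 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  if (rawToChar(raw[1:2]) != "II" || u16at(raw, 3) != 42L) {
    if (rawToChar(raw[1:2]) == "MM") return(NULL)  # big-endian: fall back
    stop("not a TIFF file: ", path)
  }
  ifd <- u32at(raw, 5)
  pages <- list()
  while (ifd != 0) {
    n <- u16at(raw, ifd + 1)
    tags <- list()
    for (i in seq_len(n)) {
      base <- ifd + 2 + (i - 1) * 12
      tag <- u16at(raw, base + 1)
      type <- u16at(raw, base + 3)
      count <- u32at(raw, base + 5)
      value <- if (type == 3L) u16at(raw, base + 9) else u32at(raw, base + 9)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = value, at = base + 9)
    }
    gv <- function(tag) tags[[as.character(tag)]]$value
    if (is.null(tags[["258"]]) || gv(258L) != 64L ||
        is.null(tags[["339"]]) || gv(339L) != 3L ||
        gv(259L) != 1L) {
      return(NULL)  # not our 64-bit float flavour
    }
    w <- gv(256L); h <- gv(257L)
    so <- tags[["273"]]; sb <- tags[["279"]]
    offs <- read_tag_longs(raw, so)
    lens <- read_tag_longs(raw, sb)
    vals <- unlist(lapply(seq_along(offs), function(j) {
      idx <- seq.int(offs[j] + 1, offs[j] + lens[j])
      readBin(raw[idx], "numeric", n = lens[j] / 8, size = 8,
              endian = "little")
    }))
    if (length(vals) != w * h) stop("corrupt TIFF strip data in ", path)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
    ifd <- u32at(raw, ifd + 2 + n * 12 + 1)
  }
  pages
}

u16at <- function(raw, i) {
  readBin(raw[i:(i + 1)], "integer", size = 2, signed = FALSE,
          endian = "little")
}
u32at <- function(raw, i) {
  v <- readBin(raw[i:(i + 3)], "integer", size = 4, endian = "little")
  if (v < 0) stop("TIFF offset exceeds 2 GiB")
  v
}

read_tag_longs <- function(raw, tag) {
  if (tag$count == 1L) return(tag$value)
  off <- tag$value
  vapply(seq_len(tag$count), function(j) u32at(raw, off + 1 + (j - 1) * 4),
         numeric(1))
}
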