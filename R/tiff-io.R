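# Minimal baseline TIFF codec (no TIFF package is available in this
# environment). Supports what the pipeline needs: uncompressed strip-based
# files, 8- or 16-bit samples, grayscale or RGB, chunky planar layout,
# either byte order. Returns/accepts the same [0, 1] double convention as
# png::readPNG / jpeg::readJPEG.

read_tiff <- function(path) {
  n <- file.size(path)
  raw <- readBin(path, "raw", n)
  if (length(raw) < 8L) stop("not a TIFF file (too short)")
  bom <- rawToChar(raw[1:2])
  endian <- switch(bom, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark)"))
  u16 <- function(off) readBin(raw[off + 0:1], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[off + 0:3], "integer", size = 4,
                               endian = endian)
  if (u16(3L) != 42L) stop("not a TIFF file (bad magic number)")
  ifd <- u32(5L) + 1L               # 1-based offset of first IFD
  n_entries <- u16(ifd)
  if (n_entries < 1L) stop("TIFF has an empty IFD")

  # read one tag's value vector (SHORT=3 or LONG=4 only)
  tag_values <- function(entry_off) {
    tag   <- u16(entry_off)
    type  <- u16(entry_off + 2L)
    count <- u32(entry_off + 4L)
    size  <- switch(as.character(type), `3` = 2L, `4` = 4L, `1` = 1L, NA_integer_)
    if (is.na(size)) return(NULL)
    rdr <- function(off, k) {
      vapply(seq_len(k) - 1L, function(i) {
        if (size == 4L) u32(off + 4L * i)
        else if (size == 2L) u16(off + 2L * i)
        else as.integer(raw[off + i])
      }, integer(1))
    }
    off <- if (count * size <= 4L) entry_off + 8L else u32(entry_off + 8L) + 1L
    list(tag = tag, values = rdr(off, count))
  }

  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- tag_values(ifd + 2L + 12L * (i - 1L))
    if (!is.null(e)) tags[[as.character(e$tag)]] <- e$values
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag)
      default
    } else v
  }

  width  <- need(256L)
  height <- need(257L)
  bits   <- unique(need(258L, 1L))
  comp   <- need(259L, 1L)
  photo  <- need(262L)
  offs   <- need(273L)
  spp    <- need(277L, 1L)
  counts <- need(279L)

  if (comp != 1L) stop("only uncompressed TIFF is supported (compression=",
                       comp, ")")
  if (length(bits) != 1L || !bits %in% c(8L, 16L)) {
    stop("only 8- or 16-bit TIFF samples are supported")
  }
  if (!photo %in% c(1L, 2L)) {
    stop("only grayscale (black-is-zero) or RGB TIFF is supported")
  }
  if (!spp %in% c(1L, 3L)) stop("unsupported TIFF samples per pixel: ", spp)

  data <- raw[unlist(Map(function(o, k) o + seq_len(k), offs, counts))]
  vals <- readBin(data, "integer", n = length(data) %/% (bits %/% 8L),
                  size = bits %/% 8L, signed = FALSE, endian = endian)
  if (length(vals) != width * height * spp) {
    stop("TIFF pixel data has unexpected length")
  }
  maxval <- 2^bits - 1
  if (spp == 1L) {
    # row-major on disk; R matrices are column-major
    m <- matrix(vals, nrow = width, ncol = height)
    t(m) / maxval
  } else {
    a <- array(vals, dim = c(3L, width, height))
    aperm(a, c(3L, 2L, 1L)) / maxval
  }
}

# Writes an uncompressed little-endian single-strip TIFF. `pixels` is an
# integer matrix (gray) or H x W x 3 array with values in [0, 2^bits - 1].
# Used for fixtures and round-trip tests.
write_tiff <- function(pixels, path, bits = 8L) {
  stopifnot(bits %in% c(8L, 16L))
  dims <- dim(pixels)
  gray <- length(dims) == 2L
  if (!gray && (length(dims) != 3L || dims[3] != 3L)) {
    stop("pixels must be a matrix or an H x W x 3 array")
  }
  h <- dims[1]; w <- dims[2]; spp <- if (gray) 1L else 3L
  if (any(pixels < 0) || any(pixels > 2^bits - 1)) {
    stop("pixel values out of range for ", bits, "-bit storage")
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  entries <- list(  # tag, type (3 SHORT / 4 LONG), count, value
    c(256L, 4L, 1L, w),
    c(257L, 4L, 1L, h),
    c(258L, 3L, spp, NA),            # BitsPerSample (offset patched below)
    c(259L, 3L, 1L, 1L),
    c(262L, 3L, 1L, if (gray) 1L else 2L),
    c(273L, 4L, 1L, NA),             # StripOffsets
    c(277L, 3L, 1L, spp),
    c(278L, 4L, 1L, h),
    c(279L, 4L, 1L, h * w * spp * (bits %/% 8L))
  )
  ifd_off <- 8L
  ifd_len <- 2L + 12L * length(entries) + 4L
  bps_off <- ifd_off + ifd_len                  # external BitsPerSample array
  bps_len <- if (spp == 3L) 6L else 0L
  data_off <- bps_off + bps_len

  writeBin(charToRaw("II"), con); wr16(42L); wr32(ifd_off)
  wr16(length(entries))
  for (e in entries) {
    wr16(e[1]); wr16(e[2]); wr32(e[3])
    if (e[1] == 258L) {
      if (spp == 3L) wr32(bps_off) else { wr16(bits); wr16(0L) }
    } else if (e[1] == 273L) {
      wr32(data_off)
    } else if (e[2] == 3L) {
      wr16(e[4]); wr16(0L)
    } else {
      wr32(e[4])
    }
  }
  wr32(0L)                                      # no next IFD
  if (spp == 3L) { wr16(bits); wr16(bits); wr16(bits) }

  vals <- if (gray) as.integer(t(pixels)) else as.integer(aperm(pixels, c(3, 2, 1)))
  writeBin(vals, con, size = bits %/% 8L, endian = "little")
  invisible(path)
}
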