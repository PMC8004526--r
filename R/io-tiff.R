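# Minimal multi-page TIFF reading for intensity stacks (read-only).
#
# Supports the subset produced by common microscopy export paths:
# uncompressed, single-sample grayscale pages of 8/16/32-bit unsigned
# integers or 32-bit IEEE floats, little- or big-endian, strip layout.
# Each page is one z-slice; pages must share width/height.

tiff_read_entry <- function(con, endian) {
  tag <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  type <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  count <- readBin(con, "integer", 1, 4, endian = endian)
  value_raw <- readBin(con, "raw", 4)
  list(tag = tag, type = type, count = count, raw = value_raw)
}

tiff_entry_values <- function(con, entry, endian) {
  sizes <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L)
  sz <- sizes[as.character(entry$type)]
  if (is.na(sz)) stopf("unsupported TIFF field type %d", entry$type)
  nbytes <- sz * entry$count
  if (nbytes <= 4) {
    raw_vals <- entry$raw[seq_len(nbytes)]
  } else {
    off <- readBin(entry$raw, "integer", 1, 4, endian = endian)
    old <- seek(con, where = NA)
    seek(con, off)
    raw_vals <- readBin(con, "raw", nbytes)
    seek(con, old)
  }
  if (entry$type == 11L)
    readBin(raw_vals, "numeric", entry$count, 4, endian = endian)
  else
    readBin(raw_vals, "integer", entry$count, sz,
            signed = sz == 4L, endian = endian)
}

read_tiff_stack_raw <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  byte_order <- rawToChar(readBin(con, "raw", 2))
  endian <- switch(byte_order, II = "little", MM = "big",
                   stopf("not a TIFF file: %s", path))
  magic <- readBin(con, "integer", 1, 2, endian = endian)
  if (magic != 42L) stopf("not a TIFF file: %s", path)
  ifd_off <- readBin(con, "integer", 1, 4, endian = endian)
  pages <- list()
  while (ifd_off != 0L) {
    seek(con, ifd_off)
    n_entries <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
    entries <- vector("list", n_entries)
    for (i in seq_len(n_entries)) entries[[i]] <- tiff_read_entry(con, endian)
    ifd_off <- readBin(con, "integer", 1, 4, endian = endian)
    tagval <- function(tag, default = NULL) {
      for (e in entries) if (e$tag == tag) return(tiff_entry_values(con, e, endian))
      default
    }
    width <- tagval(256L)
    height <- tagval(257L)
    bps <- tagval(258L, 1L)[1]
    compression <- tagval(259L, 1L)
    strip_offsets <- tagval(273L)
    rows_per_strip <- tagval(278L, height)[1]
    strip_counts <- tagval(279L)
    fmt <- tagval(339L, 1L)[1]
    spp <- tagval(277L, 1L)[1]
    if (is.null(width) || is.null(height) || is.null(strip_offsets))
      stopf("malformed TIFF IFD in %s", path)
    if (compression != 1L)
      stopf("only uncompressed TIFF is supported (compression code %d)",
            compression)
    if (spp != 1L) stopf("only single-sample (grayscale) TIFF is supported")
    if (!(bps %in% c(8L, 16L, 32L)))
      stopf("unsupported TIFF bit depth %d", bps)
    vals <- numeric(0)
    for (s in seq_along(strip_offsets)) {
      seek(con, strip_offsets[s])
      nb <- if (!is.null(strip_counts)) strip_counts[s]
            else width * rows_per_strip * bps / 8
      raw_vals <- readBin(con, "raw", nb)
      v <- if (fmt == 3L)
        readBin(raw_vals, "numeric", nb / 4, 4, endian = endian)
      else
        readBin(raw_vals, "integer", (nb * 8L) %/% bps, bps %/% 8L,
                signed = bps == 32L, endian = endian)
      vals <- c(vals, as.numeric(v))
    }
    vals <- vals[seq_len(width * height)]
    # disk layout is row-major (x fastest); page matrix is [x, y]
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = width, ncol = height)
  }
  if (!length(pages)) stopf("TIFF file contains no pages: %s", path)
  nx <- nrow(pages[[1]]); ny <- ncol(pages[[1]])
  arr <- array(0, c(length(pages), ny, nx))   # (z, y, x)
  for (z in seq_along(pages)) arr[z, , ] <- t(pages[[z]])
  arr
}

# Internal writer used by the test-suite to build fixtures for the reader:
# uncompressed little-endian grayscale, one strip per page.
write_tiff_stack_raw <- function(arr, path, bps = 32L) {
  stopifnot(length(dim(arr)) == 3L, bps %in% c(8L, 16L, 32L))
  nz <- dim(arr)[1]; ny <- dim(arr)[2]; nx <- dim(arr)[3]
  fmt <- if (bps == 32L) 3L else 1L
  bytes_pp <- nx * ny * bps %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, 2L, endian = "little")
  n_tags <- 9L
  ifd_size <- 2L + n_tags * 12L + 4L
  # layout: header(8) | page data blocks | IFDs
  data_off <- 8L
  ifd0_off <- data_off + nz * bytes_pp
  writeBin(ifd0_off, con, 4L, endian = "little")
  for (z in seq_len(nz)) {
    page <- t(arr[z, , ])                      # [x, y]: x fastest on disk
    if (fmt == 3L) writeBin(as.numeric(page), con, 4L, endian = "little")
    else writeBin(as.integer(page), con, bps %/% 8L, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, 2L, endian = "little")
    writeBin(as.integer(type), con, 2L, endian = "little")
    writeBin(as.integer(count), con, 4L, endian = "little")
    if (type == 3L) {
      writeBin(as.integer(value), con, 2L, endian = "little")
      writeBin(0L, con, 2L, endian = "little")
    } else writeBin(as.integer(value), con, 4L, endian = "little")
  }
  for (z in seq_len(nz)) {
    writeBin(as.integer(n_tags), con, 2L, endian = "little")
    entry(256L, 4L, 1L, nx)                    # ImageWidth
    entry(257L, 4L, 1L, ny)                    # ImageLength
    entry(258L, 3L, 1L, bps)                   # BitsPerSample
    entry(259L, 3L, 1L, 1L)                    # Compression: none
    entry(262L, 3L, 1L, 1L)                    # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off + (z - 1L) * bytes_pp)  # StripOffsets
    entry(278L, 4L, 1L, ny)                    # RowsPerStrip
    entry(279L, 4L, 1L, bytes_pp)              # StripByteCounts
    entry(339L, 3L, 1L, fmt)                   # SampleFormat
    next_ifd <- if (z < nz) ifd0_off + z * ifd_size else 0L
    writeBin(as.integer(next_ifd), con, 4L, endian = "little")
  }
  invisible(path)
}
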