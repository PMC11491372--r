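# Minimal baseline TIFF codec: little-endian, uncompressed, single-sample
# grayscale, multi-page. Sufficient for the plain/OME-flavoured interchange
# TIFFs this pipeline consumes and produces; no installed package provides
# TIFF I/O in this stack, so the format is implemented here directly.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `11` = 4L, `12` = 8L)

write_u <- function(con, x, size) {
  # write unsigned integers of 1/2/4 bytes, little-endian
  x <- as.numeric(x)
  half <- 2^(8 * size - 1)
  x <- ifelse(x >= half, x - 2 * half, x)
  writeBin(as.integer(x), con, size = size, endian = "little")
}

tiff_entry <- function(tag, type, count, value) {
  list(tag = tag, type = type, count = count, value = value)
}

write_ifd_entry <- function(con, e) {
  write_u(con, e$tag, 2L)
  write_u(con, e$type, 2L)
  write_u(con, e$count, 4L)
  payload <- TIFF_TYPE_SIZE[[as.character(e$type)]] * e$count
  if (e$type == 2L) {                       # ASCII: value is an offset
    write_u(con, e$value, 4L)
  } else if (payload <= 4L) {
    if (e$type == 3L) {
      write_u(con, e$value[1], 2L)
      write_u(con, if (e$count >= 2) e$value[2] else 0L, 2L)
    } else {
      write_u(con, e$value[1], 4L)
    }
  } else {
    write_u(con, e$value, 4L)               # pre-computed offset
  }
}

pixel_spec <- function(dtype) {
  switch(dtype,
    uint8   = list(bits = 8L,  fmt = 1L, size = 1L),
    uint16  = list(bits = 16L, fmt = 1L, size = 2L),
    float32 = list(bits = 32L, fmt = 3L, size = 4L),
    float64 = list(bits = 64L, fmt = 3L, size = 8L),
    stop(sprintf("unsupported dtype '%s'", dtype))
  )
}

#' Write a multi-page grayscale TIFF
#'
#' Pages are written uncompressed, little-endian, one strip per page, with an
#' optional ImageDescription on the first page.
#'
#' @param pages list of numeric matrices (rows = y, columns = x), all of the
#'   same dimensions
#' @param path output file path
#' @param dtype one of "uint8", "uint16", "float32", "float64"
#' @param description optional character scalar stored as ImageDescription
#' @return `path`, invisibly
#' @export
write_tiff <- function(pages, path, dtype = "uint16", description = NULL) {
  stopifnot(is.list(pages), length(pages) >= 1L)
  spec <- pixel_spec(dtype)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  for (p in pages) stopifnot(nrow(p) == ny, ncol(p) == nx)
  n_pages <- length(pages)
  strip_bytes <- ny * nx * spec$size

  desc <- NULL
  if (!is.null(description)) {
    desc <- c(charToRaw(as.character(description)), as.raw(0L))
    if (length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0L))
  }

  # layout: header | description | page data... | IFDs...
  off_desc <- 8L
  off_data <- off_desc + length(desc)
  data_offsets <- off_data + (seq_len(n_pages) - 1L) * strip_bytes
  off_ifd <- off_data + n_pages * strip_bytes
  n_entries <- function(i) if (i == 1L && !is.null(desc)) 11L else 10L
  ifd_size <- function(i) 2L + 12L * n_entries(i) + 4L
  ifd_offsets <- off_ifd + cumsum(c(0L, vapply(seq_len(n_pages - 1L), ifd_size, 1L)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  write_u(con, 42L, 2L)
  write_u(con, ifd_offsets[1L], 4L)
  if (!is.null(desc)) writeBin(desc, con)

  for (p in pages) {
    v <- as.numeric(t(p))                   # row-major
    if (spec$fmt == 1L) {
      top <- 2^spec$bits - 1
      if (min(v) < 0 || max(v) > top) {
        stop(sprintf("values out of range for %s", dtype))
      }
      write_u(con, round(v), spec$size)
    } else {
      writeBin(v, con, size = spec$size, endian = "little")
    }
  }

  for (i in seq_len(n_pages)) {
    entries <- list(
      tiff_entry(256L, 4L, 1L, nx),
      tiff_entry(257L, 4L, 1L, ny),
      tiff_entry(258L, 3L, 1L, spec$bits),
      tiff_entry(259L, 3L, 1L, 1L),
      tiff_entry(262L, 3L, 1L, 1L)
    )
    if (i == 1L && !is.null(desc)) {
      entries <- c(entries, list(tiff_entry(270L, 2L, length(desc), off_desc)))
    }
    entries <- c(entries, list(
      tiff_entry(273L, 4L, 1L, data_offsets[i]),
      tiff_entry(277L, 3L, 1L, 1L),
      tiff_entry(278L, 4L, 1L, ny),
      tiff_entry(279L, 4L, 1L, strip_bytes),
      tiff_entry(339L, 3L, 1L, spec$fmt)
    ))
    write_u(con, length(entries), 2L)
    for (e in entries) write_ifd_entry(con, e)
    write_u(con, if (i < n_pages) ifd_offsets[i + 1L] else 0L, 4L)
  }
  invisible(path)
}

read_u <- function(raw, offset, size, endian) {
  # read one unsigned integer from a raw vector (1-based offset)
  b <- as.integer(raw[offset:(offset + size - 1L)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1L))
}

read_tag_values <- function(raw, entry_off, endian) {
  type <- read_u(raw, entry_off + 2L, 2L, endian)
  count <- read_u(raw, entry_off + 4L, 4L, endian)
  size <- TIFF_TYPE_SIZE[[as.character(type)]]
  payload <- size * count
  off <- if (payload > 4L) read_u(raw, entry_off + 8L, 4L, endian) + 1L else entry_off + 8L
  if (type == 2L) {
    bytes <- raw[off:(off + count - 1L)]
    return(rawToChar(bytes[bytes != as.raw(0L)]))
  }
  if (type %in% c(11L, 12L)) {
    con <- rawConnection(raw[off:(off + payload - 1L)])
    on.exit(close(con))
    return(readBin(con, "double", n = count, size = size, endian = endian))
  }
  vapply(seq_len(count) - 1L, function(k) read_u(raw, off + k * size, size, endian), 1.0)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports uncompressed, single-sample, 8/16-bit unsigned or 32/64-bit float
#' data in either byte order, with any strip layout.
#'
#' @param path TIFF file path
#' @return list with `pages` (list of numeric matrices, rows = y) and
#'   `description` (ImageDescription of the first page, or `NULL`)
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF: file too short")
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF: bad byte-order mark"))
  if (read_u(raw, 3L, 2L, endian) != 42L) stop("not a TIFF: bad magic number")

  pages <- list()
  description <- NULL
  ifd_off <- read_u(raw, 5L, 4L, endian) + 1L
  while (ifd_off > 1L) {
    if (ifd_off + 1L > length(raw)) stop("corrupt TIFF: IFD beyond end of file")
    n <- read_u(raw, ifd_off, 2L, endian)
    tags <- list()
    for (k in seq_len(n)) {
      e_off <- ifd_off + 2L + (k - 1L) * 12L
      if (e_off + 11L > length(raw)) stop("corrupt TIFF: truncated IFD")
      tag <- read_u(raw, e_off, 2L, endian)
      tags[[as.character(tag)]] <- list(off = e_off)
    }
    gettag <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      read_tag_values(raw, t$off, endian)
    }
    nx <- gettag(256L); ny <- gettag(257L)
    if (is.null(nx) || is.null(ny)) stop("corrupt TIFF: missing image dimensions")
    bits <- gettag(258L, 1L)[1]
    if (gettag(259L, 1L) != 1L) stop("compressed TIFF not supported")
    if (gettag(277L, 1L) != 1L) stop("multi-sample TIFF not supported")
    fmt <- gettag(339L, 1L)[1]
    strip_offs <- gettag(273L)
    strip_counts <- gettag(279L, ny * nx * bits / 8)
    if (is.null(strip_offs)) stop("corrupt TIFF: missing strip offsets")
    if (is.null(description)) description <- gettag(270L)

    bytes <- raw(0)
    for (k in seq_along(strip_offs)) {
      s <- strip_offs[k] + 1L
      e <- s + strip_counts[k] - 1L
      if (e > length(raw)) stop("corrupt TIFF: strip beyond end of file")
      bytes <- c(bytes, raw[s:e])
    }
    size <- bits / 8L
    con <- rawConnection(bytes)
    v <- if (fmt == 3L) {
      readBin(con, "double", n = ny * nx, size = size, endian = endian)
    } else {
      readBin(con, "integer", n = ny * nx, size = size,
              signed = size < 4L, endian = endian)
    }
    close(con)
    if (length(v) < ny * nx) stop("corrupt TIFF: truncated pixel data")
    if (fmt != 3L && size == 4L) v[v < 0] <- v[v < 0] + 2^32
    m <- matrix(as.numeric(v), nrow = ny, ncol = nx, byrow = TRUE)
    pages[[length(pages) + 1L]] <- m
    ifd_off <- read_u(raw, ifd_off + 2L + n * 12L, 4L, endian) + 1L
  }
  if (length(pages) == 0L) stop("TIFF contains no images")
  list(pages = pages, description = description)
}
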