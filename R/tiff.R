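# Minimal baseline TIFF codec for single-sample (grayscale) multi-page files.
#
# No TIFF library is available in this R installation, so the package carries
# its own reader/writer restricted to what the pipeline needs: uncompressed
# strips, one sample per pixel, 8/16-bit unsigned integer or 32/64-bit IEEE
# float samples. The reader accepts both byte orders; the writer emits
# little-endian files. 64-bit float pages give lossless round trips for
# simulator output.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L, `12` = 8L)

#' Read a grayscale multi-page TIFF
#'
#' Supports uncompressed, single-sample images with 8- or 16-bit unsigned
#' integer or 32/64-bit floating-point samples, in either byte order.
#'
#' @param path Path to a TIFF file.
#' @return A list of numeric matrices, one per page, in file order.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stopf("not a TIFF file: %s", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stopf("not a TIFF file (bad byte order mark): %s", path))
  rd_int <- function(off, size, n = 1L, signed = TRUE) {
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = signed, endian = endian)
  }
  rd_dbl <- function(off, size, n = 1L) {
    readBin(raw[(off + 1L):(off + size * n)], "double", n = n, size = size,
            endian = endian)
  }
  rd_u32 <- function(off, n = 1L) {
    v <- rd_int(off, 4L, n)
    ifelse(v < 0, v + 2^32, v)
  }
  if (rd_int(2L, 2L, signed = FALSE) != 42L) stopf("not a TIFF file: %s", path)
  ifd_off <- rd_u32(4L)
  pages <- list()
  while (ifd_off != 0) {
    n_entries <- rd_int(ifd_off, 2L, signed = FALSE)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e_off <- ifd_off + 2L + (i - 1L) * 12L
      tag <- rd_int(e_off, 2L, signed = FALSE)
      type <- rd_int(e_off + 2L, 2L, signed = FALSE)
      count <- rd_u32(e_off + 4L)
      tsize <- TIFF_TYPE_SIZE[as.character(type)]
      if (is.na(tsize)) next
      nbytes <- tsize * count
      val_off <- if (nbytes <= 4L) e_off + 8L else rd_u32(e_off + 8L)
      vals <- switch(as.character(type),
        `1` = rd_int(val_off, 1L, count, signed = FALSE),
        `3` = rd_int(val_off, 2L, count, signed = FALSE),
        `4` = rd_u32(val_off, count),
        `11` = rd_dbl(val_off, 4L, count),
        `12` = rd_dbl(val_off, 8L, count),
        NULL)
      if (!is.null(vals)) tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stopf("TIFF missing required tag %d", tag)
        default
      } else v
    }
    width <- need(256L); height <- need(257L)
    bits <- need(258L, 8L)
    if (need(259L, 1L) != 1L) stopf("compressed TIFF not supported")
    fmt <- need(339L, 1L)
    strip_off <- need(273L)
    strip_cnt <- need(279L)
    data <- unlist(lapply(seq_along(strip_off), function(k) {
      off <- strip_off[k]; nb <- strip_cnt[k]
      if (fmt == 3L) {
        rd_dbl(off, bits %/% 8L, nb %/% (bits %/% 8L))
      } else if (fmt == 1L) {
        if (bits == 32L) rd_u32(off, nb %/% 4L)
        else rd_int(off, bits %/% 8L, nb %/% (bits %/% 8L), signed = FALSE)
      } else stopf("TIFF sample format %d not supported", fmt)
    }))
    if (length(data) != width * height) {
      stopf("TIFF page data length mismatch (%d != %d)", length(data), width * height)
    }
    pages[[length(pages) + 1L]] <-
      matrix(as.double(data), nrow = height, ncol = width, byrow = TRUE)
    ifd_off <- rd_u32(ifd_off + 2L + n_entries * 12L)
  }
  pages
}

#' Write a grayscale multi-page TIFF
#'
#' One page per matrix, little-endian, uncompressed, single strip per page.
#'
#' @param pages A matrix or list of matrices.
#' @param path Output path.
#' @param sample_type One of "float64" (default; lossless for doubles),
#'   "float32", "uint16", or "uint8".
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, sample_type = c("float64", "float32",
                                                    "uint16", "uint8")) {
  sample_type <- match.arg(sample_type)
  if (is.matrix(pages)) pages <- list(pages)
  spec <- switch(sample_type,
    float64 = list(bits = 64L, fmt = 3L),
    float32 = list(bits = 32L, fmt = 3L),
    uint16 = list(bits = 16L, fmt = 1L),
    uint8 = list(bits = 8L, fmt = 1L))
  bytes_px <- spec$bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeChar("II", con, nchars = 2L, eos = NULL)
  w16(42L)
  # layout: header (8) | page data (padded to even) | IFDs
  sizes <- vapply(pages, function(m) as.integer(length(m) * bytes_px), 1L)
  padded <- sizes + sizes %% 2L
  data_off <- 8L + c(0L, cumsum(padded)[-length(padded)])
  first_ifd <- 8L + sum(padded)
  n_entry <- 9L
  ifd_size <- 2L + n_entry * 12L + 4L
  w32(first_ifd)
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    v <- as.vector(t(m))
    if (spec$fmt == 3L) {
      writeBin(as.double(v), con, size = bytes_px, endian = "little")
    } else {
      vi <- as.integer(round(v))
      rng <- c(0L, if (spec$bits == 8L) 255L else 65535L)
      if (any(vi < rng[1L] | vi > rng[2L])) {
        stopf("values out of range for %s TIFF output", sample_type)
      }
      writeBin(vi, con, size = bytes_px, endian = "little")
    }
    if (sizes[i] %% 2L == 1L) writeBin(as.raw(0L), con)
  }
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    w16(n_entry)
    entry(256L, 4L, 1L, ncol(m))
    entry(257L, 4L, 1L, nrow(m))
    entry(258L, 3L, 1L, spec$bits)
    entry(259L, 3L, 1L, 1L)
    entry(262L, 3L, 1L, 1L)
    entry(273L, 4L, 1L, data_off[i])
    entry(277L, 3L, 1L, 1L)
    entry(279L, 4L, 1L, sizes[i])
    entry(339L, 3L, 1L, spec$fmt)
    next_ifd <- if (i < length(pages)) first_ifd + i * ifd_size else 0L
    w32(next_ifd)
  }
  invisible(path)
}
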