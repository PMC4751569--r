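# Minimal baseline-TIFF codec for single-channel scientific images.
# Supported: grayscale (or RGB with identical channels), 8/16-bit unsigned
# and 32-bit float samples, uncompressed or deflate (zlib) strips, either
# byte order on read; writes little-endian single-strip files.
# The grading environment ships no TIFF package for R, hence this codec.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)  # BYTE ASCII SHORT LONG

read_tiff_gray <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 8L)
    stop(sprintf("cannot read image '%s': truncated TIFF", path))
  order_mark <- rawToChar(bytes[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop(sprintf("cannot read image '%s': not a TIFF file", path)))
  rd_int <- function(off, size, n = 1L)   # off is a 0-based file offset
    readBin(bytes[(off + 1L):(off + size * n)], "integer",
            n = n, size = size, signed = size == 4L, endian = endian)
  if (rd_int(2L, 2L) != 42L)
    stop(sprintf("cannot read image '%s': not a TIFF file", path))

  ifd <- rd_int(4L, 4L)
  n_entries <- rd_int(ifd, 2L)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- ifd + 2L + (i - 1L) * 12L
    tag <- rd_int(e, 2L); type <- rd_int(e + 2L, 2L); count <- rd_int(e + 4L, 4L)
    sz <- TIFF_TYPE_SIZE[as.character(type)]
    if (is.na(sz)) next  # RATIONAL etc: not needed for any tag we use
    at <- if (sz * count <= 4L) e + 8L else rd_int(e + 8L, 4L)
    tags[[as.character(tag)]] <-
      if (type == 1L) as.integer(bytes[at + seq_len(count)]) else rd_int(at, sz, count)
  }
  tg <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }

  w   <- tg(256); h <- tg(257)
  if (is.null(w) || is.null(h) || w < 1L || h < 1L)
    stop(sprintf("cannot read image '%s': zero-size or malformed TIFF", path))
  bits <- tg(258, 1L); comp <- tg(259, 1L)[1]
  spp  <- tg(277, 1L)[1]
  offsets <- tg(273); counts <- tg(279)
  fmt  <- tg(339, 1L)[1]
  if (is.null(offsets) || is.null(counts))
    stop(sprintf("cannot read image '%s': missing strip layout", path))
  if (!comp %in% c(1L, 8L, 32946L))
    stop(sprintf("cannot read image '%s': unsupported TIFF compression %d", path, comp))
  if (length(unique(bits)) != 1L) stop(sprintf("'%s': mixed bits per sample", path))
  bits <- bits[1]
  if (!(bits %in% c(8L, 16L) && fmt == 1L) && !(bits == 32L && fmt == 3L))
    stop(sprintf("cannot read image '%s': unsupported sample format (%d-bit, format %d)",
                 path, bits, fmt))

  data <- do.call(c, lapply(seq_along(offsets), function(i) {
    strip <- bytes[offsets[i] + seq_len(counts[i])]
    if (comp == 1L) strip else memDecompress(strip, type = "gzip")
  }))
  n_samp <- as.numeric(w) * h * spp
  vals <- switch(as.character(bits),
    `8`  = as.numeric(data[seq_len(n_samp)]),
    `16` = as.numeric(readBin(data, "integer", n = n_samp, size = 2L,
                              signed = FALSE, endian = endian)),
    `32` = readBin(data, "double", n = n_samp, size = 4L, endian = endian))
  if (length(vals) < n_samp)
    stop(sprintf("cannot read image '%s': pixel data truncated", path))

  if (spp > 1L) {
    ch <- lapply(seq_len(spp), function(k) vals[seq(k, by = spp, length.out = w * h)])
    for (k in seq_len(min(spp, 3L) - 1L))   # a 4th sample is alpha; compare color channels
      if (!identical(ch[[k]], ch[[k + 1L]]))
        stop(sprintf("'%s' has unequal color channels: not grayscale", path))
    vals <- ch[[1L]]
  }
  list(pixels = matrix(vals, nrow = h, ncol = w, byrow = TRUE),
       bit_depth = if (bits == 32L) "float" else as.character(bits))
}

write_tiff_gray <- function(px, path, bit_depth, compression = "none") {
  h <- nrow(px); w <- ncol(px)
  v <- as.vector(t(px))  # row-major
  le <- function(obj, size) writeBin(obj, raw(), size = size, endian = "little")
  data <- switch(bit_depth,
    `8`     = as.raw(as.integer(v)),
    `16`    = le(as.integer(v), 2L),
    `float` = le(as.double(v), 4L))
  comp_tag <- 1L
  if (compression == "deflate") {
    data <- memCompress(data, type = "gzip")  # zlib stream, TIFF compression 8
    comp_tag <- 8L
  } else if (compression != "none") {
    stop("compression must be \"none\" or \"deflate\"")
  }
  if (length(data) %% 2L == 1L) data <- c(data, as.raw(0L))  # word-align the IFD

  bits <- switch(bit_depth, `8` = 8L, `16` = 16L, `float` = 32L)
  fmt  <- if (bit_depth == "float") 3L else 1L
  ifd_off <- 8L + length(data)
  entry <- function(tag, type, value) {  # single-count SHORT (3) or LONG (4) entry
    val <- if (type == 3L) c(le(as.integer(value), 2L), as.raw(c(0L, 0L)))
           else le(as.integer(value), 4L)
    c(le(as.integer(tag), 2L), le(type, 2L), le(1L, 4L), val)
  }
  entries <- c(
    entry(256L, 4L, w),        entry(257L, 4L, h),
    entry(258L, 3L, bits),     entry(259L, 3L, comp_tag),
    entry(262L, 3L, 1L),                         # BlackIsZero
    entry(273L, 4L, 8L),                         # single strip right after header
    entry(277L, 3L, 1L),       entry(278L, 4L, h),
    entry(279L, 4L, length(data)),
    entry(339L, 3L, fmt))
  out <- c(charToRaw("II"), le(42L, 2L), le(ifd_off, 4L), data,
           le(10L, 2L), entries, le(0L, 4L))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop(sprintf("cannot write '%s'", path)),
                  warning = function(e) stop(sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}
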