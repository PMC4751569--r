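# 16-bit grayscale PNG writer. The png package reads 16-bit files but only
# writes 8-bit ones, so deep phantoms are written here: zlib via
# memCompress, chunk CRCs via digest's crc32.

write_png16_gray <- function(px, path) {
  h <- nrow(px); w <- ncol(px)
  v <- as.integer(t(px))                       # row-major, values in [0, 65535]
  sample_bytes <- as.raw(rbind(v %/% 256L, v %% 256L))   # big-endian pairs
  rows <- matrix(sample_bytes, nrow = 2L * w, ncol = h)
  scanlines <- as.raw(rbind(matrix(as.raw(0L), 1L, h), rows))  # filter byte 0

  u32be <- function(x) as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256,
                                (x %/% 256) %% 256, x %% 256))
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    hex <- formatC(digest::digest(body, algo = "crc32", serialize = FALSE),
                   width = 8, flag = "0")
    crc <- u32be(strtoi(substr(hex, 1, 4), 16L) * 65536 +
                 strtoi(substr(hex, 5, 8), 16L))
    c(u32be(length(data)), body, crc)
  }
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           chunk("IHDR", ihdr),
           chunk("IDAT", memCompress(scanlines, type = "gzip")),
           chunk("IEND", raw(0)))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop(sprintf("cannot write '%s'", path)),
                  warning = function(e) stop(sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}
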