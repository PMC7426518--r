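# Minimal 16-bit grayscale PNG encoder. The installed PNG bindings read
# 16-bit images but only write 8 bits per sample; tumor MRI intensities need
# the full 16-bit range to round-trip losslessly, so the writer emits the
# PNG container directly (IHDR / IDAT with a zlib stream from memCompress /
# IEND, CRC32 computed here).

.crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) {
        bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))
      } else {
        bitwShiftR(bitwAnd(c, -2L), 1) # logical shift of c with LSB cleared
      }
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  b <- as.integer(bytes)
  for (x in b) {
    idx <- bitwAnd(bitwXor(crc, x), 255L)
    crc <- bitwXor(.crc32_table[idx + 1], bitwShiftR(bitwAnd(crc, -256L), 8))
  }
  bitwXor(crc, -1L)
}

int_to_be4 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body)
  # map signed int to unsigned 32-bit big-endian
  u <- if (crc < 0) 4294967296 + crc else crc
  c(int_to_be4(length(data)), body, int_to_be4(u))
}

# m: integer matrix (row = image row from top), values in [0, 65535]
write_png16 <- function(m, path) {
  stopifnot(is.matrix(m))
  v <- as.integer(round(m))
  if (anyNA(v) || any(v < 0L) || any(v > 65535L)) {
    stop("write_png16: values must be integers in [0, 65535]")
  }
  h <- nrow(m); w <- ncol(m)
  # scanlines: filter byte 0, then big-endian uint16 pixels, row by row
  mm <- matrix(v, h, w)
  hi <- as.raw(t(mm) %/% 256L)
  lo <- as.raw(t(mm) %% 256L)
  px <- as.raw(rbind(hi, lo))        # interleave high/low byte per pixel
  dim(px) <- c(2L * w, h)
  scan <- rbind(matrix(as.raw(0L), 1, h), px)
  ihdr <- c(int_to_be4(w), int_to_be4(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  idat <- memCompress(as.raw(scan), type = "gzip") # zlib stream (RFC 1950)
  out <- c(
    as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", idat),
    png_chunk("IEND", raw(0))
  )
  writeBin(out, path)
  invisible(path)
}
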