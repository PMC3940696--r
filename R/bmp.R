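# Minimal BMP codec: uncompressed (BI_RGB) 24- and 32-bit Windows bitmaps,
# bottom-up or top-down row order. Enough to honor .bmp inputs without an
# external decoder; the writer emits 24-bit bottom-up files and exists mainly
# so round trips can be tested.

.read_bmp <- function(path) {
  sz <- file.info(path)$size
  b <- readBin(path, "raw", n = sz)
  if (length(b) < 54 || b[1] != as.raw(0x42) || b[2] != as.raw(0x4D)) {
    stop("not a BMP file: ", path, call. = FALSE)
  }
  u16 <- function(i) as.integer(b[i]) + 256L * as.integer(b[i + 1])
  u32 <- function(i) as.integer(b[i]) + 256L * (as.integer(b[i + 1]) +
          256L * (as.integer(b[i + 2]) + 256L * as.integer(b[i + 3])))
  data_off <- u32(11)
  hdr_size <- u32(15)
  if (hdr_size < 40) stop("unsupported BMP header", call. = FALSE)
  w <- u32(19)
  h_raw <- u32(23)
  top_down <- h_raw > 2^31 - 1
  h <- if (top_down) 2^32 - h_raw else h_raw
  bpp <- u16(29)
  compression <- u32(31)
  if (!(bpp %in% c(24L, 32L)) || compression != 0) {
    stop("only uncompressed 24/32-bit BMP is supported (got ", bpp,
         "-bit, compression ", compression, ")", call. = FALSE)
  }
  bytes_pp <- bpp %/% 8L
  stride <- ((w * bytes_pp + 3L) %/% 4L) * 4L
  px <- as.integer(b[(data_off + 1):(data_off + stride * h)])
  rows <- matrix(px, nrow = stride, ncol = h) # column = one stored row
  row_order <- if (top_down) seq_len(h) else rev(seq_len(h))
  nch <- if (bytes_pp == 4L) 4L else 3L # alpha as 4th plane when present
  img <- array(0L, dim = c(h, w, nch))
  col_idx <- (seq_len(w) - 1L) * bytes_pp
  for (r in seq_len(h)) {
    stored <- rows[, row_order[r]]
    img[r, , 1] <- stored[col_idx + 3L] # BGR(A) order on disk
    img[r, , 2] <- stored[col_idx + 2L]
    img[r, , 3] <- stored[col_idx + 1L]
    if (nch == 4L) img[r, , 4] <- stored[col_idx + 4L]
  }
  img
}

.write_bmp <- function(img, path) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  stride <- ((w * 3L + 3L) %/% 4L) * 4L
  data_size <- stride * h
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
  u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
  header <- c(as.raw(c(0x42, 0x4D)), u32(54 + data_size), u16(0), u16(0),
              u32(54),
              u32(40), u32(w), u32(h), u16(1), u16(24), u32(0),
              u32(data_size), u32(2835), u32(2835), u32(0), u32(0))
  img <- .clamp255(round(img))
  body <- raw(data_size)
  col_idx <- (seq_len(w) - 1L) * 3L
  for (r in seq_len(h)) { # bottom-up
    off <- (h - r) * stride
    row <- integer(stride)
    row[col_idx + 1L] <- img[r, , 3]
    row[col_idx + 2L] <- img[r, , 2]
    row[col_idx + 3L] <- img[r, , 1]
    body[off + seq_len(stride)] <- as.raw(row)
  }
  writeBin(c(header, body), path)
  invisible(path)
}
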