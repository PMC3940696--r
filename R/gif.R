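# Minimal GIF codec. Reader: GIF87a/89a, global/local color tables, LZW
# decompression, interlace; animated files decode to the first image only.
# Writer: single-frame GIF with a "clear-code" LZW stream (valid, merely
# uncompressed), used for round-trip testing of the reader.

.read_gif <- function(path) {
  sz <- file.info(path)$size
  b <- readBin(path, "raw", n = sz)
  if (length(b) < 13 || rawToChar(b[1:3]) != "GIF") {
    stop("not a GIF file: ", path, call. = FALSE)
  }
  u16 <- function(i) as.integer(b[i]) + 256L * as.integer(b[i + 1])
  packed <- as.integer(b[11])
  pos <- 14L
  gct <- NULL
  if (bitwAnd(packed, 0x80) > 0) {
    n <- 2L^(bitwAnd(packed, 0x07) + 1L)
    gct <- matrix(as.integer(b[pos:(pos + 3L * n - 1L)]), nrow = 3L)
    pos <- pos + 3L * n
  }
  repeat {
    if (pos > length(b)) stop("truncated GIF: ", path, call. = FALSE)
    marker <- as.integer(b[pos])
    if (marker == 0x3B) stop("GIF contains no image data", call. = FALSE)
    if (marker == 0x21) { # extension: label + sub-blocks
      pos <- pos + 2L
      while (as.integer(b[pos]) != 0L) pos <- pos + as.integer(b[pos]) + 1L
      pos <- pos + 1L
    } else if (marker == 0x2C) {
      break
    } else {
      stop("unexpected GIF block 0x", format(as.hexmode(marker)),
           call. = FALSE)
    }
  }
  w <- u16(pos + 5L); h <- u16(pos + 7L)
  ipacked <- as.integer(b[pos + 9L])
  pos <- pos + 10L
  ct <- gct
  if (bitwAnd(ipacked, 0x80) > 0) {
    n <- 2L^(bitwAnd(ipacked, 0x07) + 1L)
    ct <- matrix(as.integer(b[pos:(pos + 3L * n - 1L)]), nrow = 3L)
    pos <- pos + 3L * n
  }
  if (is.null(ct)) stop("GIF has no color table", call. = FALSE)
  interlaced <- bitwAnd(ipacked, 0x40) > 0
  mcs <- as.integer(b[pos]); pos <- pos + 1L
  data <- raw(0)
  while (as.integer(b[pos]) != 0L) {
    n <- as.integer(b[pos])
    data <- c(data, b[(pos + 1L):(pos + n)])
    pos <- pos + n + 1L
  }
  idx <- .lzw_decode(data, mcs, w * h)
  if (length(idx) < w * h) stop("GIF pixel data truncated", call. = FALSE)
  idx <- idx[seq_len(w * h)] + 1L        # 1-based into color table
  m <- matrix(idx, nrow = w)             # column = one image row
  rows <- t(m)
  if (interlaced) {
    order <- c(seq(1L, h, 8L),
               if (h >= 5L) seq(5L, h, 8L),
               if (h >= 3L) seq(3L, h, 4L),
               if (h >= 2L) seq(2L, h, 2L))
    rows[order, ] <- rows
  }
  img <- array(0L, dim = c(h, w, 3L))
  img[, , 1] <- ct[1, rows]
  img[, , 2] <- ct[2, rows]
  img[, , 3] <- ct[3, rows]
  img
}

.lzw_decode <- function(bytes, mcs, n_expected) {
  bits <- as.integer(rawToBits(bytes)) # LSB-first, the GIF bit order
  clear <- 2L^mcs
  eoi <- clear + 1L
  pow2 <- 2L^(0:11)
  dict <- vector("list", 4096L)
  for (i in seq_len(clear)) dict[[i]] <- i - 1L
  reset <- function() list(width = mcs + 1L, nxt = eoi + 1L)
  st <- reset()
  out <- vector("list", n_expected)
  n_out <- 0L
  prev <- NULL
  pos <- 1L
  nbits <- length(bits)
  while (pos + st$width - 1L <= nbits) {
    code <- sum(bits[pos:(pos + st$width - 1L)] * pow2[seq_len(st$width)])
    pos <- pos + st$width
    if (code == clear) {
      st <- reset(); prev <- NULL
      next
    }
    if (code == eoi) break
    if (code < st$nxt) {
      entry <- dict[[code + 1L]]
      if (!is.null(prev) && st$nxt < 4096L) {
        dict[[st$nxt + 1L]] <- c(prev, entry[1L])
        st$nxt <- st$nxt + 1L
      }
    } else if (code == st$nxt && !is.null(prev)) {
      entry <- c(prev, prev[1L])
      if (st$nxt < 4096L) {
        dict[[st$nxt + 1L]] <- entry
        st$nxt <- st$nxt + 1L
      }
    } else {
      stop("corrupt LZW stream in GIF", call. = FALSE)
    }
    n_out <- n_out + 1L
    out[[n_out]] <- entry
    prev <- entry
    if (st$nxt == 2L^st$width && st$width < 12L) st$width <- st$width + 1L
    if (n_out >= n_expected) {
      total <- sum(lengths(out[seq_len(n_out)]))
      if (total >= n_expected) break
    }
  }
  unlist(out[seq_len(n_out)], use.names = FALSE)
}

.write_gif <- function(img, path) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  img <- .clamp255(round(img))
  h <- dim(img)[1]; w <- dim(img)[2]
  key <- img[, , 1] * 65536 + img[, , 2] * 256 + img[, , 3]
  cols <- sort(unique(as.vector(key)))
  if (length(cols) > 256L) {
    stop("GIF writer supports at most 256 distinct colors", call. = FALSE)
  }
  idx0 <- matrix(match(key, cols) - 1L, h, w) # 0-based palette index
  gct_bits <- max(1L, ceiling(log2(max(2L, length(cols)))))
  tbl_n <- 2L^gct_bits
  ct <- integer(3L * tbl_n)
  ct[3 * seq_along(cols) - 2] <- cols %/% 65536
  ct[3 * seq_along(cols) - 1] <- (cols %/% 256) %% 256
  ct[3 * seq_along(cols)] <- cols %% 256
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
  mcs <- max(2L, gct_bits)
  clear <- 2L^mcs
  # literal-only stream: clear codes keep the decoder's table from growing
  # past the fixed code width
  stream <- as.vector(t(idx0)) # row-major pixel order
  width <- mcs + 1L
  budget <- 2L^mcs - 2L
  codes <- integer(0)
  acc <- integer(length(stream) + ceiling(length(stream) / max(1L, budget)) + 2L)
  n <- 0L
  add <- function(code) { n <<- n + 1L; acc[n] <<- code }
  add(clear)
  count <- 0L
  for (px in stream) {
    if (count >= budget) { add(clear); count <- 0L }
    add(px)
    count <- count + 1L
  }
  add(clear + 1L) # end of information
  acc <- acc[seq_len(n)]
  bits <- logical(n * width)
  for (k in seq_len(width)) {
    bits[seq(k, by = width, length.out = n)] <- bitwAnd(acc, 2L^(k - 1L)) > 0
  }
  bytes <- packBits(c(bits, logical((8 - length(bits) %% 8) %% 8)), type = "raw")
  blocks <- raw(0)
  i <- 1L
  while (i <= length(bytes)) {
    j <- min(i + 254L, length(bytes))
    blocks <- c(blocks, as.raw(j - i + 1L), bytes[i:j])
    i <- j + 1L
  }
  out <- c(charToRaw("GIF89a"), u16(w), u16(h),
           as.raw(bitwOr(0x80, bitwOr(0x70, gct_bits - 1L))), as.raw(0),
           as.raw(0),
           as.raw(ct),
           as.raw(0x2C), u16(0), u16(0), u16(w), u16(h), as.raw(0),
           as.raw(mcs), blocks, as.raw(0), as.raw(0x3B))
  writeBin(out, path)
  invisible(path)
}
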