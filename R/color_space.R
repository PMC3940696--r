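#' RGB to HSV conversion on the 8-bit histology scale
#'
#' Converts 8-bit RGB colors to the HSV parameterization used throughout this
#' package: hue in degrees on `[0, 360]`, saturation and value on `[0, 255]`.
#' The hexcone mapping is: `V = max(R, G, B)`; `S = 255 * (MAX - MIN) / MAX`
#' (0 when `MAX = 0`); hue is piecewise linear in the channel differences,
#' with the branch selected by which channel attains the maximum, and 360 is
#' added when the red branch yields a negative angle.
#'
#' Two degenerate cases are defined explicitly so the map is total:
#' achromatic pixels (`MAX = MIN`) take `H = 0` with `S = 0` marking them as
#' gray, and black (`MAX = 0`) takes `S = 0`. Ties for the maximum channel are
#' broken with fixed priority R, then G, then B; at a tie boundary every
#' branch yields the same hue, so the priority only fixes bit-reproducibility.
#'
#' @param x an RGB triple (numeric length 3), an `n x 3` matrix of triples,
#'   or an `h x w x 3` image array; channel values in `[0, 255]`.
#' @return An object of the same shape holding `(H, S, V)` as doubles.
#' @examples
#' rgb_to_hsv(c(255, 0, 0))        # pure red: H = 0, S = 255, V = 255
#' rgb_to_hsv(c(128, 0, 128))      # dark violet: H = 300
#' @seealso [hsv_to_rgb()], [convert_image()]
#' @export
rgb_to_hsv <- function(x) {
  chan <- .split_channels(x, c("R", "G", "B"))
  out <- .rgb_to_hsv_num(chan$c1, chan$c2, chan$c3)
  .rebuild_channels(out$h, out$s, out$v, chan, c("H", "S", "V"))
}

#' HSV to RGB conversion (inverse mapping)
#'
#' Inverts [rgb_to_hsv()]: hue in degrees on `[0, 360]` (360 treated as 0),
#' saturation and value on `[0, 255]`, back to RGB on `[0, 255]`. Zero
#' saturation yields the gray `(V, V, V)` regardless of hue. For any RGB
#' triple with distinct channel values the round trip
#' `hsv_to_rgb(rgb_to_hsv(q))` recovers `q` exactly after rounding to the
#' nearest integer.
#'
#' @param x an HSV triple, `n x 3` matrix, or `h x w x 3` array.
#' @param round logical; round the result to integers (default `TRUE`).
#' @return RGB values in the same shape as `x`.
#' @examples
#' hsv_to_rgb(c(0, 255, 255))   # (255, 0, 0)
#' @export
hsv_to_rgb <- function(x, round = TRUE) {
  chan <- .split_channels(x, c("H", "S", "V"))
  out <- .hsv_to_rgb_num(chan$c1, chan$c2, chan$c3)
  if (round) {
    out <- lapply(out, function(v) round(v))
  }
  .rebuild_channels(out$r, out$g, out$b, chan, c("R", "G", "B"))
}

#' Convert a whole raster image between RGB and HSV
#'
#' Applies [rgb_to_hsv()] or [hsv_to_rgb()] pixelwise to an `h x w x 3`
#' array, preserving dimensions. The result carries a `"space"` attribute
#' (`"HSV"` or `"RGB"`) that the thresholding engine uses to detect
#' mismatched inputs.
#'
#' @param img an `h x w x 3` numeric array.
#' @param to target space, `"HSV"` or `"RGB"`.
#' @return Converted array of identical dimensions.
#' @export
convert_image <- function(img, to = c("HSV", "RGB")) {
  to <- match.arg(to)
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  out <- if (to == "HSV") rgb_to_hsv(img) else hsv_to_rgb(img)
  attr(out, "space") <- to
  alpha <- attr(img, "alpha", exact = TRUE)
  if (!is.null(alpha)) attr(out, "alpha") <- alpha
  out
}

#' Color space of an image array
#'
#' Reads the `"space"` attribute attached by [convert_image()] and the image
#' readers; arrays without one are taken to be RGB, the storage space of
#' essentially all digital images.
#'
#' @param img image array.
#' @return `"RGB"` or `"HSV"`.
#' @export
image_space <- function(img) {
  sp <- attr(img, "space", exact = TRUE)
  if (is.null(sp)) "RGB" else sp
}

## vectorized core: r, g, b numeric vectors in [0, 255]
.rgb_to_hsv_num <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  delta <- mx - mn
  h <- numeric(length(r))
  chrom <- delta > 0
  # max-channel branch, fixed priority R -> G -> B on ties
  is_r <- chrom & (r == mx)
  is_g <- chrom & !is_r & (g == mx)
  is_b <- chrom & !is_r & !is_g
  h[is_r] <- 60 * (g[is_r] - b[is_r]) / delta[is_r]
  h[is_g] <- 60 * (2 + (b[is_g] - r[is_g]) / delta[is_g])
  h[is_b] <- 60 * (4 + (r[is_b] - g[is_b]) / delta[is_b])
  h[h < 0] <- h[h < 0] + 360
  s <- ifelse(mx > 0, delta / mx * 255, 0)
  list(h = h, s = s, v = mx)
}

.hsv_to_rgb_num <- function(h, s, v) {
  h <- h %% 360
  sector <- floor(h / 60)
  f <- h / 60 - sector
  sn <- s / 255
  p <- v * (1 - sn)
  q <- v * (1 - f * sn)
  t <- v * (1 - (1 - f) * sn)
  r <- g <- b <- numeric(length(h))
  for (k in 0:5) {
    i <- sector == k
    if (!any(i)) next
    ch <- switch(as.character(k),
      "0" = list(v[i], t[i], p[i]),
      "1" = list(q[i], v[i], p[i]),
      "2" = list(p[i], v[i], t[i]),
      "3" = list(p[i], q[i], v[i]),
      "4" = list(t[i], p[i], v[i]),
      "5" = list(v[i], p[i], q[i])
    )
    r[i] <- ch[[1]]; g[i] <- ch[[2]]; b[i] <- ch[[3]]
  }
  list(r = r, g = g, b = b)
}

## shape-preserving channel plumbing shared by the two converters
.split_channels <- function(x, names3) {
  if (is.array(x) && length(dim(x)) == 3L) {
    stopifnot(dim(x)[3] == 3L)
    list(c1 = as.numeric(x[, , 1]), c2 = as.numeric(x[, , 2]),
         c3 = as.numeric(x[, , 3]), shape = "image", dim = dim(x))
  } else if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    list(c1 = as.numeric(x[, 1]), c2 = as.numeric(x[, 2]),
         c3 = as.numeric(x[, 3]), shape = "matrix", dim = dim(x))
  } else {
    stopifnot(is.numeric(x), length(x) == 3L)
    list(c1 = x[1], c2 = x[2], c3 = x[3], shape = "triple", dim = NULL)
  }
}

.rebuild_channels <- function(c1, c2, c3, chan, names3) {
  switch(chan$shape,
    image = array(c(c1, c2, c3), dim = chan$dim),
    matrix = {
      m <- cbind(c1, c2, c3)
      colnames(m) <- names3
      m
    },
    triple = stats::setNames(c(c1, c2, c3), names3)
  )
}

.clamp255 <- function(x) pmin(pmax(x, 0), 255)
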