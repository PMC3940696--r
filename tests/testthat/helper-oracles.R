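# Independent scalar oracles, written as plain transcriptions of the
# definitions; the package implementations are vectorized and must agree
# with these exactly.

# hexcone RGB -> HSV for one pixel, H in [0,360], S/V in [0,255]
oracle_rgb_to_hsv <- function(r, g, b) {
  mx <- max(r, g, b)
  mn <- min(r, g, b)
  v <- mx
  if (mx == 0) return(c(0, 0, 0))
  s <- (mx - mn) / mx * 255
  if (mx == mn) return(c(0, s, v))
  d <- mx - mn
  h <- if (r == mx) {           # R >= G, B (tie priority R, G, B)
    60 * (g - b) / d
  } else if (g == mx) {
    60 * (2 + (b - r) / d)
  } else {
    60 * (4 + (r - g) / d)
  }
  if (h < 0) h <- h + 360
  c(h, s, v)
}

# closed-interval cuboid membership with an explicit two-interval hue test
oracle_in_cuboid <- function(p, cuboid) {
  r <- cuboid$ranges
  if (cuboid$space == "HSV") {
    hmin <- r$h[1]; hmax <- r$h[2]
    in_h <- if (hmax > 360) {
      # wrap: [hmin, 360] U [0, hmax - 360]
      (p[1] >= hmin & p[1] <= 360) | (p[1] >= 0 & p[1] <= hmax - 360)
    } else {
      p[1] >= hmin & p[1] <= hmax
    }
    in_h && p[2] >= r$s[1] && p[2] <= r$s[2] &&
      p[3] >= r$v[1] && p[3] <= r$v[2]
  } else {
    p[1] >= r$r[1] && p[1] <= r$r[2] &&
      p[2] >= r$g[1] && p[2] <= r$g[2] &&
      p[3] >= r$b[1] && p[3] <= r$b[2]
  }
}

# triple-loop pixel counting oracle over an image + ROI
oracle_counts <- function(img, ts, roi) {
  h <- dim(img)[1]; w <- dim(img)[2]
  counts_ind <- integer(length(ts$cuboids))
  counts_exc <- integer(length(ts$cuboids))
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!roi[i, j]) next
      p <- img[i, j, ]
      taken <- FALSE
      for (k in seq_along(ts$cuboids)) {
        if (oracle_in_cuboid(p, ts$cuboids[[k]])) {
          counts_ind[k] <- counts_ind[k] + 1L
          if (!taken) {
            counts_exc[k] <- counts_exc[k] + 1L
            taken <- TRUE
          }
        }
      }
    }
  }
  list(independent = counts_ind, exclusive = counts_exc)
}

random_rgb_image <- function(h, w, seed = 1) {
  set.seed(seed)
  img <- array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  storage.mode(img) <- "integer"
  attr(img, "space") <- "RGB"
  img
}

tiny_scene <- function(size = 96, seed = 1, ...) {
  generate_scene(synthetic_scene(size, size, seed = seed, ...))
}
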