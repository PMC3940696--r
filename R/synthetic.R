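#' Default trichrome-like tissue classes
#'
#' Base colors emulating a Masson's-trichrome-stained infarcted section:
#' scarlet-red muscle (hue ~8 deg), aniline-blue collagen (hue ~231 deg) and,
#' optionally, a dark purple necrotic core (low value, hue ~291 deg). Area
#' fractions default to 45% muscle and 20% collagen (plus 5% necrotic when
#' requested); the remainder is near-white slide background.
#'
#' @param necrotic include the third (necrotic) class?
#' @return List of class descriptors `(label, color, fraction)`.
#' @export
trichrome_classes <- function(necrotic = FALSE) {
  cls <- list(
    list(label = "muscle", color = c(205, 70, 48), fraction = 0.45),
    list(label = "collagen", color = c(55, 75, 190), fraction = 0.20)
  )
  if (necrotic) {
    cls <- c(cls, list(list(label = "necrotic", color = c(70, 40, 75),
                            fraction = 0.05)))
  }
  cls
}

#' Describe a synthetic stained-section scene
#'
#' A parametric stand-in for a stained histological section: distinct-hue
#' tissue classes with exact target area fractions on a near-white
#' background, with per-pixel Gaussian jitter of saturation and value
#' emulating the stain-density gradient always present in real sections.
#' Hue jitter is off by default — hue is the variable the HSV method relies
#' on — but can be enabled to stress hue thresholds.
#'
#' @param width,height image size in pixels.
#' @param classes list of `(label, color = RGB triple, fraction)` entries,
#'   listed from the outermost tissue band inward; see [trichrome_classes()].
#'   Fractions must be positive and sum to at most 1.
#' @param geometry `"infarct"` (nested blob: last class innermost),
#'   `"blobs"` (several seeded foci) or `"wedges"` (angular sectors).
#' @param background RGB triple of the unstained background.
#' @param jitter_sv standard deviation of the Gaussian S/V jitter
#'   (8-bit units; default 10).
#' @param jitter_h standard deviation of hue jitter in degrees (default 0).
#' @param seed integer RNG seed; a fixed seed makes [generate_scene()]
#'   byte-reproducible.
#' @return A `synthetic_scene` specification.
#' @export
synthetic_scene <- function(width, height, classes = trichrome_classes(),
                            geometry = c("infarct", "blobs", "wedges"),
                            background = c(247, 245, 235),
                            jitter_sv = 10, jitter_h = 0, seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(width >= 1, height >= 1, length(classes) >= 1)
  fr <- vapply(classes, `[[`, numeric(1), "fraction")
  if (any(fr <= 0) || any(fr >= 1) || sum(fr) > 1) {
    stop("class area fractions must lie in (0, 1) and sum to at most 1",
         call. = FALSE)
  }
  stopifnot(jitter_sv >= 0, jitter_h >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 classes = classes, geometry = geometry,
                 background = as.numeric(background),
                 jitter_sv = jitter_sv, jitter_h = jitter_h,
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' Generate a synthetic stained-section image with ground truth
#'
#' Renders the scene to an 8-bit RGB image together with its ground-truth
#' label mask. Class regions are carved out of a smooth random scalar field
#' by rank, so each class occupies exactly `round(fraction * width * height)`
#' pixels — the label mask is definitional truth for all downstream
#' percent-area checks. All randomness (field shape, jitter) derives from
#' the scene seed.
#'
#' @param scene a [synthetic_scene()].
#' @return List with `image` (`h x w x 3` integer RGB array), `labels`
#'   (integer matrix, 0 = background, k = k-th class), `class_counts`
#'   (named vector) and the `scene`.
#' @export
generate_scene <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  w <- scene$width; h <- scene$height
  n <- w * h
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(scene$seed)

  xs <- matrix(rep(seq_len(w), each = h), h, w) / w
  ys <- matrix(rep(seq_len(h), times = w), h, w) / h
  field <- switch(scene$geometry,
    infarct = {
      cx <- 0.5 + stats::runif(1, -0.1, 0.1)
      cy <- 0.5 + stats::runif(1, -0.1, 0.1)
      d <- sqrt((xs - cx)^2 + (ys - cy)^2)
      d + .bump_noise(xs, ys, n_bumps = 6, amp = 0.08)
    },
    blobs = {
      k <- 4L
      cx <- stats::runif(k, 0.15, 0.85); cy <- stats::runif(k, 0.15, 0.85)
      d <- Reduce(pmin, lapply(seq_len(k), function(i) {
        sqrt((xs - cx[i])^2 + (ys - cy[i])^2)
      }))
      d + .bump_noise(xs, ys, n_bumps = 4, amp = 0.05)
    },
    wedges = {
      off <- stats::runif(1, 0, 2 * pi)
      (atan2(ys - 0.5, xs - 0.5) + off) %% (2 * pi)
    }
  )

  fr <- vapply(scene$classes, `[[`, numeric(1), "fraction")
  counts <- round(fr * n)
  k_cls <- length(counts)
  ord <- order(as.vector(field))
  labels <- integer(n)
  pos <- 0L
  for (k in rev(seq_len(k_cls))) { # last listed class is innermost
    if (counts[k] > 0) labels[ord[(pos + 1L):(pos + counts[k])]] <- k
    pos <- pos + counts[k]
  }
  labels <- matrix(labels, h, w)

  img <- .colorize_labels(labels, scene)
  cc <- stats::setNames(as.integer(counts),
                        vapply(scene$classes, `[[`, character(1), "label"))
  list(image = img, labels = labels, class_counts = cc, scene = scene)
}

## smooth random field from a few Gaussian bumps
.bump_noise <- function(xs, ys, n_bumps, amp) {
  z <- 0
  for (i in seq_len(n_bumps)) {
    bx <- stats::runif(1); by <- stats::runif(1)
    s <- stats::runif(1, 0.08, 0.25)
    a <- stats::runif(1, -amp, amp)
    z <- z + a * exp(-((xs - bx)^2 + (ys - by)^2) / (2 * s^2))
  }
  z
}

.colorize_labels <- function(labels, scene) {
  h <- nrow(labels); w <- ncol(labels)
  base <- c(list(scene$background),
            lapply(scene$classes, `[[`, "color"))
  if (scene$jitter_sv == 0 && scene$jitter_h == 0) {
    img <- array(0L, dim = c(h, w, 3L))
    for (k in 1:3) {
      ch <- matrix(0L, h, w)
      for (lab in 0:(length(base) - 1L)) {
        ch[labels == lab] <- as.integer(base[[lab + 1L]][k])
      }
      img[, , k] <- ch
    }
  } else {
    hh <- ss <- vv <- matrix(0, h, w)
    for (lab in 0:(length(base) - 1L)) {
      hsv <- rgb_to_hsv(base[[lab + 1L]])
      sel <- labels == lab
      hh[sel] <- hsv[1]; ss[sel] <- hsv[2]; vv[sel] <- hsv[3]
    }
    n <- h * w
    if (scene$jitter_sv > 0) {
      ss <- .clamp255(ss + stats::rnorm(n, 0, scene$jitter_sv))
      vv <- .clamp255(vv + stats::rnorm(n, 0, scene$jitter_sv))
    }
    if (scene$jitter_h > 0) {
      hh <- (hh + stats::rnorm(n, 0, scene$jitter_h)) %% 360
    }
    hsv_img <- array(c(hh, ss, vv), dim = c(h, w, 3L))
    img <- hsv_to_rgb(hsv_img)
    storage.mode(img) <- "integer"
  }
  attr(img, "space") <- "RGB"
  img
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate section-thickness change
#'
#' A thicker section binds more stain and transmits less light: saturation
#' scales up and value scales down by a common factor `t`, hue is untouched.
#' Per pixel the image is converted to HSV, `S' = clamp(S * t, 0, 255)`,
#' `V' = clamp(V / t, 0, 255)`, and converted back; `t = 1` is the identity
#' up to integer rounding. Exact hue preservation is the mechanism behind
#' the robustness of hue-anchored thresholds to thickness variation.
#'
#' @param img `h x w x 3` RGB array.
#' @param t thickness scale factor, `> 0` (`t = 1` neutral).
#' @return Transformed RGB array.
#' @export
apply_thickness <- function(img, t) {
  stopifnot(is.numeric(t), length(t) == 1L, t > 0)
  hsv <- convert_image(img, "HSV")
  hsv[, , 2] <- .clamp255(hsv[, , 2] * t)
  hsv[, , 3] <- .clamp255(hsv[, , 3] / t)
  out <- hsv_to_rgb(hsv)
  storage.mode(out) <- "integer"
  attr(out, "space") <- "RGB"
  out
}

#' Simulate a tissue fold
#'
#' A fold stacks two or three tissue layers: within the folded region the
#' section behaves like one `layers` times thicker, so the thickness
#' transform with `t = layers` is applied there and pixels outside the
#' region are left unchanged. Hue is preserved inside the fold.
#'
#' @param img `h x w x 3` RGB array.
#' @param region logical mask of the folded region (image dimensions), or an
#'   `n x 2` matrix of polygon vertices `(x, y)` in pixel coordinates (see
#'   [polygon_mask()]).
#' @param layers 2 or 3.
#' @return RGB array with the fold applied.
#' @export
apply_fold <- function(img, region, layers = 2L) {
  stopifnot(layers %in% c(2L, 3L))
  d <- dim(img)[1:2]
  if (is.matrix(region) && !is.logical(region)) {
    if (any(region[, 1] < 1) || any(region[, 1] > d[2]) ||
        any(region[, 2] < 1) || any(region[, 2] > d[1])) {
      stop("fold region polygon lies outside the image", call. = FALSE)
    }
    region <- polygon_mask(region, width = d[2], height = d[1])
  }
  stopifnot(is.logical(region))
  if (!identical(dim(region), d)) {
    stop("fold region does not match image dimensions", call. = FALSE)
  }
  folded <- apply_thickness(img, as.numeric(layers))
  out <- img
  for (k in 1:3) {
    ch <- out[, , k]; fc <- folded[, , k]
    ch[region] <- fc[region]
    out[, , k] <- ch
  }
  attr(out, "space") <- "RGB"
  out
}

#' Rasterize a polygon to a logical mask
#'
#' Even-odd (crossing-number) rasterization of a closed polygon; pixel
#' centers at integer coordinates, `x` = column, `y` = row.
#'
#' @param vertices `n x 2` matrix of `(x, y)` vertices.
#' @param width,height mask dimensions.
#' @return `height x width` logical matrix.
#' @export
polygon_mask <- function(vertices, width, height) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2L, nrow(vertices) >= 3L)
  xs <- rep(seq_len(width), each = height)
  ys <- rep(seq_len(height), times = width)
  n <- nrow(vertices)
  inside <- logical(width * height)
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    cross <- ((yi > ys) != (yj > ys)) &
      (xs < (xj - xi) * (ys - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  matrix(inside, height, width)
}

#' Simulate a tilted-slide defocus gradient
#'
#' Applies a Gaussian blur whose radius (sigma, in pixels) ramps linearly
#' from 0 at the top edge to `max_radius` at the bottom edge, emulating the
#' focal-plane gradient produced by a tilted slide. Rows are linear blends
#' of integer-radius blurred copies; `max_radius = 0` is the identity.
#'
#' @param img `h x w x 3` RGB array.
#' @param max_radius maximum blur sigma at the far edge, `>= 0`.
#' @return Blurred RGB array (integer, clamped).
#' @export
apply_defocus <- function(img, max_radius) {
  stopifnot(is.numeric(max_radius), length(max_radius) == 1L, max_radius >= 0)
  if (max_radius == 0) return(img)
  h <- dim(img)[1]
  levels <- 0:ceiling(max_radius)
  r_row <- if (h == 1L) max_radius else max_radius * (seq_len(h) - 1) / (h - 1)
  out <- array(0, dim = dim(img))
  for (l in levels) {
    wgt <- pmax(0, 1 - abs(r_row - l))
    if (all(wgt == 0)) next
    bl <- if (l == 0) {
      img * 1.0
    } else {
      e <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
      # Gaussian kernel must fit inside the image
      rad <- min(2L * ceiling(3 * l) + 1L, min(dim(img)[1:2]))
      if (rad %% 2L == 0L) rad <- rad - 1L
      b <- EBImage::gblur(e, sigma = l, radius = rad, boundary = "replicate")
      aperm(EBImage::imageData(b), c(2, 1, 3)) * 255
    }
    out <- out + bl * wgt # recycles over rows (dim 1)
  }
  out <- .clamp255(round(out))
  storage.mode(out) <- "integer"
  attr(out, "space") <- "RGB"
  out
}

#' Downsample an image by area averaging
#'
#' Reduces each dimension by the linear factor `k`, averaging `k x k` pixel
#' blocks; trailing blocks of non-divisible dimensions are averaged over the
#' available pixels, so the output size is `ceiling(dim / k)` (a 3000-pixel
#' side at `k = 16` gives 188). Area averaging preserves the image mean
#' exactly for divisible dimensions (before rounding).
#'
#' @param img `h x w x 3` RGB array.
#' @param k integer linear reduction factor (2, 4, 8 or 16 in the resolution
#'   experiments; any `k >= 1` accepted).
#' @param round round the result to integers (default `TRUE`).
#' @return Downsampled RGB array.
#' @export
downsample_image <- function(img, k, round = TRUE) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  d <- dim(img)
  if (d[1] < k || d[2] < k) {
    stop("image (", d[1], "x", d[2], ") smaller than factor ", k,
         call. = FALSE)
  }
  if (k == 1L) return(img)
  gr <- ceiling(seq_len(d[1]) / k)
  gc <- ceiling(seq_len(d[2]) / k)
  nr <- max(gr); nc <- max(gc)
  cnt <- tabulate(gr, nr) %o% tabulate(gc, nc)
  out <- array(0, dim = c(nr, nc, 3L))
  for (ch in 1:3) {
    s <- rowsum(img[, , ch], gr)          # nr x w
    s <- t(rowsum(t(s), gc))              # nr x nc
    out[, , ch] <- s / cnt
  }
  if (round) {
    out <- round(out)
    storage.mode(out) <- "integer"
  }
  attr(out, "space") <- "RGB"
  out
}

#' Write a generated scene to disk
#'
#' Emits the rendered image (PNG), the ground-truth label mask (grayscale
#' PNG holding the raw class indices) and a CSV of per-class pixel counts.
#'
#' @param gen result of [generate_scene()].
#' @param dir output directory (created if needed).
#' @param name base file name (default `"scene"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scene <- function(gen, dir, name = "scene") {
  stopifnot(is.list(gen), !is.null(gen$image), !is.null(gen$labels))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_img <- file.path(dir, paste0(name, ".png"))
  p_lab <- file.path(dir, paste0(name, "_labels.png"))
  p_csv <- file.path(dir, paste0(name, "_truth.csv"))
  write_image(gen$image, p_img)
  png::writePNG(gen$labels / 255, p_lab)
  df <- data.frame(label = c("background", names(gen$class_counts)),
                   pixels = c(sum(gen$labels == 0L), as.integer(gen$class_counts)))
  utils::write.csv(df, p_csv, row.names = FALSE, quote = FALSE)
  invisible(c(image = p_img, labels = p_lab, truth = p_csv))
}
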