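#' Project image pixels onto a color-plane density map
#'
#' Bins the ROI pixels of an HSV (or RGB) image into a 2-D histogram over
#' one coordinate plane of the color space — the view used to place and
#' inspect threshold cuboids: Hue-Saturation, Hue-Value or Saturation-Value
#' (R-G, R-B, G-B for RGB images). The histogram always covers the full axis
#' ranges (hue `[0, 360]`, other axes `[0, 255]`) and its total mass equals
#' the ROI pixel count exactly.
#'
#' @param img `h x w x 3` image array; its [image_space()] decides which
#'   planes are valid.
#' @param plane `"HS"`, `"HV"`, `"SV"` — or `"RG"`, `"RB"`, `"GB"`.
#' @param roi optional logical ROI matrix; default whole image.
#' @param bins number of bins per axis (scalar or length 2), at least 2.
#' @return A `density_map` object: count matrix `bins` (axis1 rows, axis2
#'   columns), `edges1`/`edges2` bin edges, axis names, and `n` (ROI pixels).
#' @export
project_density <- function(img, plane, roi = NULL, bins = 128) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  sp <- image_space(img)
  planes <- if (sp == "HSV") c("HS", "HV", "SV") else c("RG", "RB", "GB")
  plane <- toupper(plane)
  if (!plane %in% planes) {
    stop("plane must be one of ", paste(planes, collapse = ", "),
         " for a ", sp, " image", call. = FALSE)
  }
  bins <- rep(as.integer(bins), length.out = 2L)
  stopifnot(all(bins >= 2L))
  roi <- .resolve_roi(img, roi)
  ax <- strsplit(plane, "")[[1]]
  axis_names <- strsplit(sp, "")[[1]]
  k1 <- match(ax[1], axis_names)
  k2 <- match(ax[2], axis_names)
  x1 <- img[, , k1][roi]
  x2 <- img[, , k2][roi]
  r1 <- if (ax[1] == "H") 360 else 255
  r2 <- if (ax[2] == "H") 360 else 255
  i1 <- pmin(bins[1], floor(x1 / r1 * bins[1]) + 1L)
  i2 <- pmin(bins[2], floor(x2 / r2 * bins[2]) + 1L)
  counts <- matrix(tabulate((i2 - 1L) * bins[1] + i1, nbins = bins[1] * bins[2]),
                   nrow = bins[1], ncol = bins[2])
  structure(list(space = sp, plane = plane,
                 axis1 = ax[1], axis2 = ax[2],
                 bins = counts,
                 edges1 = seq(0, r1, length.out = bins[1] + 1L),
                 edges2 = seq(0, r2, length.out = bins[2] + 1L),
                 n = length(x1)),
            class = "density_map")
}

#' Render a density map with threshold rectangles
#'
#' Produces a raster heat map of the binned counts (log-scaled for display;
#' the stored counts stay linear) with the projection of each threshold
#' cuboid drawn as a rectangle outline in its display color. When a cuboid's
#' hue interval wraps past 360 and hue is one of the plot axes, the axis is
#' extended up to the cuboid's upper hue bound, the low-hue columns are
#' duplicated past 360, and the cuboid appears as a single rectangle
#' crossing the 360 line — the conventional way to show a red-straddling
#' threshold.
#'
#' @param map a `density_map` from [project_density()].
#' @param cuboids list of [threshold_cuboid()] in the map's space (may be
#'   empty).
#' @param px integer magnification: output pixels per bin (default 2).
#' @return `h x w x 3` RGB array; the vertical axis is flipped so axis 2
#'   increases upward as in a plot.
#' @export
render_density <- function(map, cuboids = list(), px = 2L) {
  stopifnot(inherits(map, "density_map"))
  if (inherits(cuboids, "threshold_cuboid")) cuboids <- list(cuboids)
  if (inherits(cuboids, "threshold_set")) cuboids <- cuboids$cuboids
  for (cb in cuboids) {
    if (cb$space != map$space) {
      stop("cuboid space ", cb$space, " does not match map space ",
           map$space, call. = FALSE)
    }
  }
  px <- max(1L, as.integer(px))
  counts <- map$bins
  lim1 <- max(map$edges1)
  lim2 <- max(map$edges2)
  # extend a hue axis past 360 when a cuboid wraps
  wrap_max <- 0
  if (map$space == "HSV") {
    hmaxs <- vapply(cuboids, function(cb) cb$ranges$h[2], numeric(1))
    if (length(hmaxs) && any(hmaxs > 360)) wrap_max <- max(hmaxs)
  }
  if (wrap_max > 360 && map$axis1 == "H") {
    bw <- diff(map$edges1)[1]
    extra <- ceiling((wrap_max - 360) / bw)
    counts <- rbind(counts, counts[seq_len(extra), , drop = FALSE])
    lim1 <- 360 + extra * bw
  }
  n1 <- nrow(counts); n2 <- ncol(counts)
  val <- log1p(counts)
  top <- max(val)
  idx <- if (top > 0) pmin(255L, floor(val / top * 255)) + 1L else
    matrix(1L, n1, n2)
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis"))
  w <- n1 * px; h <- n2 * px
  col_of <- function(k) matrix(pal[k, idx], n1, n2)
  img <- array(0, dim = c(h, w, 3L))
  rows <- rev(rep(seq_len(n2), each = px))   # flip so axis2 increases upward
  cols <- rep(seq_len(n1), each = px)
  for (k in 1:3) img[, , k] <- t(col_of(k)[cols, ])[rows, ]

  ax_lim <- c(lim1, lim2)
  to_px1 <- function(v) pmin(w, pmax(1L, round(v / ax_lim[1] * (w - 1)) + 1L))
  to_px2 <- function(v) pmin(h, pmax(1L, round(v / ax_lim[2] * (h - 1)) + 1L))
  for (cb in cuboids) {
    axkey <- function(a) tolower(a)
    rr1 <- cb$ranges[[axkey(map$axis1)]]
    rr2 <- cb$ranges[[axkey(map$axis2)]]
    if (map$axis1 == "H" && wrap_max <= 360 && rr1[2] > 360) {
      rr1 <- c(rr1[1], 360) # no extended axis available on this plane
    }
    c0 <- to_px1(rr1[1]); c1 <- to_px1(min(rr1[2], ax_lim[1]))
    r1p <- h - to_px2(min(rr2[2], ax_lim[2])) + 1L
    r2p <- h - to_px2(rr2[1]) + 1L
    col <- cb$display_color
    for (k in 1:3) {
      img[r1p, c0:c1, k] <- col[k]
      img[r2p, c0:c1, k] <- col[k]
      img[r1p:r2p, c0, k] <- col[k]
      img[r1p:r2p, c1, k] <- col[k]
    }
  }
  storage.mode(img) <- "integer"
  attr(img, "space") <- "RGB"
  img
}

#' Dump / load the raw bin grid of a density map
#'
#' Plain-text CSV of the count matrix, one row per axis-1 bin, for external
#' plotting or archiving.
#'
#' @param map a `density_map`.
#' @param path destination `.csv`.
#' @return `path`, invisibly.
#' @export
write_density <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  utils::write.table(map$bins, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @export
print.density_map <- function(x, ...) {
  cat("Density map ", x$plane, " (", x$space, " space): ",
      nrow(x$bins), "x", ncol(x$bins), " bins, ", x$n, " pixels\n", sep = "")
  invisible(x)
}
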