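#' Define a threshold cuboid in HSV or RGB space
#'
#' A threshold cuboid is an axis-aligned box in a 3-D color space; a pixel is
#' positive for the cuboid only when all three of its components lie inside
#' the corresponding closed `[min, max]` interval. In HSV space the hue axis
#' is circular: an interval may extend past 360 (up to 720) to straddle the
#' red wrap-around, e.g. `h = c(300, 385)` selects hues in
#' `[300, 360] U [0, 25]`. Membership of hue `H` is tested for both `H` and
#' `H + 360`.
#'
#' @param colorspace `"HSV"` or `"RGB"`. (Named so that no abbreviated axis
#'   argument in `...` can partially match it.)
#' @param ... exactly three named length-2 numeric ranges: `h`, `s`, `v` for
#'   HSV or `r`, `g`, `b` for RGB (any order, case-insensitive).
#' @param label short name for the selected color population
#'   (e.g. `"collagen"`).
#' @param display_color RGB triple used to recolor positive pixels in
#'   overlays.
#' @return A `threshold_cuboid` object.
#' @examples
#' threshold_cuboid("HSV", h = c(300, 385), s = c(30, 255), v = c(60, 255),
#'                  label = "muscle", display_color = c(255, 0, 0))
#' @export
threshold_cuboid <- function(colorspace = c("HSV", "RGB"), ..., label = "class",
                             display_color = c(255, 0, 0)) {
  space <- match.arg(colorspace)
  axes <- if (space == "HSV") c("h", "s", "v") else c("r", "g", "b")
  rng <- list(...)
  names(rng) <- tolower(names(rng))
  if (!setequal(names(rng), axes)) {
    stop("cuboid in ", space, " space needs ranges named ",
         paste(axes, collapse = ", "), call. = FALSE)
  }
  rng <- rng[axes]
  for (a in axes) {
    v <- rng[[a]]
    if (!is.numeric(v) || length(v) != 2L || anyNA(v)) {
      stop("range '", a, "' must be numeric length 2", call. = FALSE)
    }
    if (v[1] > v[2]) stop("range '", a, "' has min > max", call. = FALSE)
    hi <- if (space == "HSV" && a == "h") 720 else if (a == "h") 360 else 255
    if (v[1] < 0 || v[2] > hi) {
      stop("range '", a, "' outside [0, ", hi, "]", call. = FALSE)
    }
  }
  stopifnot(is.numeric(display_color), length(display_color) == 3L)
  structure(list(space = space, ranges = rng, label = as.character(label),
                 display_color = as.numeric(display_color)),
            class = "threshold_cuboid")
}

#' Bundle 1-3 threshold cuboids into a threshold set
#'
#' Up to three independent color populations can be extracted in one pass,
#' mirroring the three threshold-parameter groups of the original analysis
#' workflow. All cuboids must live in the same color space.
#'
#' @param ... one to three [threshold_cuboid()] objects (or a single list of
#'   them).
#' @param background_color RGB triple painted on in-ROI pixels that match no
#'   cuboid in overlays; default yellow.
#' @return A `threshold_set` object.
#' @export
threshold_set <- function(..., background_color = c(255, 255, 0)) {
  cuboids <- list(...)
  if (length(cuboids) == 1L && !inherits(cuboids[[1]], "threshold_cuboid")) {
    cuboids <- cuboids[[1]]
  }
  if (length(cuboids) < 1L || length(cuboids) > 3L) {
    stop("a threshold set holds 1 to 3 cuboids", call. = FALSE)
  }
  ok <- vapply(cuboids, inherits, logical(1), "threshold_cuboid")
  if (!all(ok)) stop("all elements must be threshold_cuboid objects", call. = FALSE)
  spaces <- vapply(cuboids, `[[`, character(1), "space")
  if (length(unique(spaces)) != 1L) {
    stop("all cuboids in a set must share one color space", call. = FALSE)
  }
  labels <- vapply(cuboids, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("cuboid labels must be unique", call. = FALSE)
  structure(list(space = spaces[1], cuboids = cuboids,
                 background_color = as.numeric(background_color)),
            class = "threshold_set")
}

#' Test a single pixel against a cuboid
#'
#' A pixel is positive only if all three channel conditions hold
#' simultaneously; hue is tested with wrap semantics (both `H` and `H + 360`
#' against the interval).
#'
#' @param p color triple in the cuboid's space.
#' @param cuboid a [threshold_cuboid()].
#' @param space space of `p`, checked against the cuboid (default: assume
#'   matching).
#' @return Logical scalar.
#' @export
pixel_in_cuboid <- function(p, cuboid, space = cuboid$space) {
  stopifnot(inherits(cuboid, "threshold_cuboid"))
  if (!identical(space, cuboid$space)) {
    stop("pixel is in ", space, " space but cuboid is in ", cuboid$space,
         call. = FALSE)
  }
  stopifnot(is.numeric(p), length(p) == 3L)
  as.logical(.cuboid_mask(p[1], p[2], p[3], cuboid))
}

## vectorized membership; a1..a3 are the three channels in cuboid order
.cuboid_mask <- function(a1, a2, a3, cuboid) {
  r <- cuboid$ranges
  if (cuboid$space == "HSV") {
    in1 <- (a1 >= r$h[1] & a1 <= r$h[2]) |
           (a1 + 360 >= r$h[1] & a1 + 360 <= r$h[2])
    in2 <- a2 >= r$s[1] & a2 <= r$s[2]
    in3 <- a3 >= r$v[1] & a3 <= r$v[2]
  } else {
    in1 <- a1 >= r$r[1] & a1 <= r$r[2]
    in2 <- a2 >= r$g[1] & a2 <= r$g[2]
    in3 <- a3 >= r$b[1] & a3 <= r$b[2]
  }
  in1 & in2 & in3
}

#' Apply a threshold set to an image
#'
#' Classifies every ROI pixel against each cuboid, counts positive area, and
#' renders a recolored overlay. Counts are reported two ways: `independent`
#' counts test each cuboid on its own (a pixel inside two overlapping cuboids
#' is counted for both), while `exclusive` counts assign each pixel to the
#' first matching cuboid in list order so that class counts plus the
#' unassigned count partition the ROI exactly. Percent positive area is
#' `100 * count / roi_pixel_count`.
#'
#' The overlay recolors each positive pixel (exclusive assignment) to its
#' cuboid's display color and every other ROI pixel to the set's background
#' color; pixels outside the ROI keep their original appearance.
#'
#' @param img `h x w x 3` image array whose space (see [image_space()])
#'   matches the threshold set.
#' @param ts a [threshold_set()].
#' @param roi optional logical matrix (same `h x w`) marking the region of
#'   interest; default is the whole image, minus fully transparent pixels
#'   when the image carries an alpha channel.
#' @param mode which counts populate `$counts` / `$percent_area`:
#'   `"exclusive"` (default) or `"independent"`. Both are always available
#'   as `$counts_exclusive` / `$counts_independent` etc.
#' @return An `extraction_result` list: per-cuboid masks, counts, percent
#'   areas, `roi_pixel_count`, the overlay image and the unassigned count.
#' @export
apply_threshold_set <- function(img, ts, roi = NULL,
                                mode = c("exclusive", "independent")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ts, "threshold_set"))
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  sp <- image_space(img)
  if (!identical(sp, ts$space)) {
    stop("image is in ", sp, " space but threshold set is in ", ts$space,
         call. = FALSE)
  }
  d <- dim(img)[1:2]
  roi <- .resolve_roi(img, roi)
  n_roi <- sum(roi)

  a1 <- img[, , 1]; a2 <- img[, , 2]; a3 <- img[, , 3]
  labels <- vapply(ts$cuboids, `[[`, character(1), "label")
  masks_ind <- lapply(ts$cuboids, function(cb) {
    m <- .cuboid_mask(a1, a2, a3, cb) & roi
    dim(m) <- d
    m
  })
  names(masks_ind) <- labels
  # first-match exclusive assignment
  claimed <- matrix(FALSE, d[1], d[2])
  masks_exc <- vector("list", length(masks_ind))
  for (i in seq_along(masks_ind)) {
    masks_exc[[i]] <- masks_ind[[i]] & !claimed
    claimed <- claimed | masks_ind[[i]]
  }
  names(masks_exc) <- labels

  counts_ind <- vapply(masks_ind, sum, integer(1))
  counts_exc <- vapply(masks_exc, sum, integer(1))
  pct_ind <- 100 * counts_ind / n_roi
  pct_exc <- 100 * counts_exc / n_roi

  overlay <- .render_overlay(img, sp, roi, masks_exc, ts)

  res <- list(
    labels = labels,
    masks = if (mode == "exclusive") masks_exc else masks_ind,
    masks_exclusive = masks_exc,
    masks_independent = masks_ind,
    counts = if (mode == "exclusive") counts_exc else counts_ind,
    counts_exclusive = counts_exc,
    counts_independent = counts_ind,
    percent_area = if (mode == "exclusive") pct_exc else pct_ind,
    percent_exclusive = pct_exc,
    percent_independent = pct_ind,
    unassigned = n_roi - sum(counts_exc),
    roi_pixel_count = n_roi,
    overlay = overlay,
    mode = mode,
    space = sp
  )
  class(res) <- "extraction_result"
  res
}

#' Extract three color populations at once
#'
#' Convenience wrapper over [apply_threshold_set()] that insists on a full
#' three-cuboid set, the configuration used to pull muscle, collagen and a
#' third population (e.g. necrotic tissue) out of one trichrome section.
#'
#' @inheritParams apply_threshold_set
#' @return An `extraction_result`; see [apply_threshold_set()].
#' @export
extract_three_colors <- function(img, ts, roi = NULL,
                                 mode = c("exclusive", "independent")) {
  stopifnot(inherits(ts, "threshold_set"))
  if (length(ts$cuboids) != 3L) {
    stop("extract_three_colors needs a set of exactly 3 cuboids",
         call. = FALSE)
  }
  apply_threshold_set(img, ts, roi = roi, mode = match.arg(mode))
}

#' Compare HSV- and RGB-space selections on one image
#'
#' Runs an HSV threshold set and an RGB threshold set on the same RGB image
#' and reports where they agree and disagree: the agreement mask (both
#' methods positive for any of their cuboids), the RGB-only mask and the
#' HSV-only mask, plus a merge overlay using the conventional colors —
#' yellow for agreement, green where only the RGB selection fires (candidate
#' false positives of the RGB method), red where only the HSV selection
#' fires (candidate RGB false negatives).
#'
#' @param img `h x w x 3` RGB image.
#' @param ts_hsv [threshold_set()] in HSV space.
#' @param ts_rgb [threshold_set()] in RGB space.
#' @param roi optional logical ROI matrix.
#' @return A `method_comparison` list with masks `agreement`, `rgb_only`,
#'   `hsv_only`, their counts, and `$overlay`.
#' @export
compare_methods <- function(img, ts_hsv, ts_rgb, roi = NULL) {
  stopifnot(inherits(ts_hsv, "threshold_set"), inherits(ts_rgb, "threshold_set"))
  if (ts_hsv$space != "HSV" || ts_rgb$space != "RGB") {
    stop("ts_hsv must be in HSV space and ts_rgb in RGB space", call. = FALSE)
  }
  if (!identical(image_space(img), "RGB")) {
    stop("compare_methods expects an RGB image", call. = FALSE)
  }
  roi <- .resolve_roi(img, roi)
  hsv_res <- apply_threshold_set(convert_image(img, "HSV"), ts_hsv, roi = roi)
  rgb_res <- apply_threshold_set(img, ts_rgb, roi = roi)
  hsv_pos <- Reduce(`|`, hsv_res$masks_independent)
  rgb_pos <- Reduce(`|`, rgb_res$masks_independent)
  agreement <- hsv_pos & rgb_pos
  rgb_only <- rgb_pos & !hsv_pos
  hsv_only <- hsv_pos & !rgb_pos

  overlay <- img
  overlay <- .paint(overlay, agreement, c(255, 255, 0))
  overlay <- .paint(overlay, rgb_only, c(0, 255, 0))
  overlay <- .paint(overlay, hsv_only, c(255, 0, 0))
  overlay <- .clamp255(round(overlay))
  storage.mode(overlay) <- "integer"
  dim(overlay) <- dim(img)
  attr(overlay, "space") <- "RGB"

  structure(list(
    agreement = agreement, rgb_only = rgb_only, hsv_only = hsv_only,
    counts = c(agreement = sum(agreement), rgb_only = sum(rgb_only),
               hsv_only = sum(hsv_only)),
    roi_pixel_count = sum(roi),
    overlay = overlay,
    hsv_result = hsv_res, rgb_result = rgb_res
  ), class = "method_comparison")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("Color extraction (", x$space, " space, ", x$mode, " counts)\n", sep = "")
  cat("ROI pixels:", x$roi_pixel_count, "\n")
  df <- data.frame(label = x$labels,
                   pixel_count = x$counts,
                   percent_area = sprintf("%.4f", x$percent_area),
                   row.names = NULL, check.names = FALSE)
  print(df, row.names = FALSE)
  cat("unassigned:", x$unassigned, "\n")
  invisible(x)
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("HSV vs RGB selection comparison\n")
  print(x$counts)
  invisible(x)
}

.resolve_roi <- function(img, roi) {
  d <- dim(img)[1:2]
  if (is.null(roi)) {
    alpha <- attr(img, "alpha", exact = TRUE)
    roi <- if (is.null(alpha)) matrix(TRUE, d[1], d[2]) else alpha > 0
  }
  stopifnot(is.logical(roi))
  if (!identical(dim(roi), d)) {
    stop("ROI dimensions ", paste(dim(roi), collapse = "x"),
         " do not match image ", paste(d, collapse = "x"), call. = FALSE)
  }
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  roi
}

## paint color onto masked pixels of an RGB array
.paint <- function(img, mask, color) {
  color <- as.integer(round(color))
  for (k in 1:3) {
    ch <- img[, , k]
    ch[mask] <- color[k]
    img[, , k] <- ch
  }
  img
}

.render_overlay <- function(img, sp, roi, masks_exc, ts) {
  base <- if (sp == "HSV") convert_image(img, "RGB") else img
  out <- .paint(base, roi, ts$background_color)
  for (i in seq_along(masks_exc)) {
    out <- .paint(out, masks_exc[[i]], ts$cuboids[[i]]$display_color)
  }
  out <- .clamp255(round(out))
  storage.mode(out) <- "integer"
  dim(out) <- dim(img)
  attr(out, "space") <- "RGB"
  out
}
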