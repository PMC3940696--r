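#' Fit per-class threshold cuboids from a labeled reference image
#'
#' Reproducible stand-in for the manual threshold tuning a user performs on
#' a single reference image: for every ground-truth class the 1st-99th
#' percentile range of the class pixels defines the interval, widened by a
#' small symmetric margin (a human sets sliders with slack, not at the exact
#' percentile). In HSV space only the hue interval is fit this way — hue is
#' the axis that separates stains — while saturation and value are left at
#' full width `[0, 255]` so the cuboid spans the whole S/V excursion caused
#' by thickness and fold artifacts. In RGB space all three channels get
#' percentile boxes, the natural analogue for the baseline method. The same
#' percentile probabilities and margin are used for both spaces so neither
#' method is favored structurally.
#'
#' Hue percentiles are wrap-aware: when a class straddles the 0/360 line its
#' hues are unwrapped past 360 first, so the fitted interval may have an
#' upper bound above 360 (hue-wrap cuboid).
#'
#' @param img `h x w x 3` RGB reference image.
#' @param labels integer label matrix (0 = background, `k` = class `k`), as
#'   produced by [generate_scene()].
#' @param space `"HSV"` or `"RGB"`.
#' @param class_names optional character names for classes `1..K`.
#' @param probs two percentile probabilities (default `c(0.01, 0.99)`).
#' @param margin symmetric widening of each fitted interval: hue degrees in
#'   HSV, intensity units in RGB (default 5).
#' @return A [threshold_set()] with one cuboid per class, display colors
#'   red / blue / black for classes 1-3.
#' @export
fit_class_thresholds <- function(img, labels, space = c("HSV", "RGB"),
                                 class_names = NULL,
                                 probs = c(0.01, 0.99), margin = 5) {
  space <- match.arg(space)
  stopifnot(is.matrix(labels), identical(dim(labels), dim(img)[1:2]))
  ks <- sort(unique(labels[labels > 0L]))
  if (length(ks) < 1L || length(ks) > 3L) {
    stop("need 1-3 ground-truth classes, found ", length(ks), call. = FALSE)
  }
  if (is.null(class_names)) class_names <- paste0("class", ks)
  palette <- list(c(255, 0, 0), c(0, 0, 255), c(0, 0, 0))
  data <- if (space == "HSV") convert_image(img, "HSV") else img

  cuboids <- lapply(seq_along(ks), function(i) {
    sel <- labels == ks[i]
    c1 <- data[, , 1][sel]; c2 <- data[, , 2][sel]; c3 <- data[, , 3][sel]
    if (space == "HSV") {
      h <- c1
      if (max(h) - min(h) > 180) h[h < 180] <- h[h < 180] + 360 # wrap-aware
      q <- stats::quantile(h, probs, names = FALSE)
      lo <- q[1] - margin; hi <- q[2] + margin
      if (lo < 0) { lo <- lo + 360; hi <- hi + 360 }
      if (lo >= 360) { lo <- lo - 360; hi <- hi - 360 }
      hi <- min(hi, 720)
      threshold_cuboid("HSV", h = c(max(0, lo), hi),
                       s = c(0, 255), v = c(0, 255),
                       label = class_names[i], display_color = palette[[i]])
    } else {
      box <- lapply(list(c1, c2, c3), function(v) {
        q <- stats::quantile(v, probs, names = FALSE)
        c(max(0, q[1] - margin), min(255, q[2] + margin))
      })
      threshold_cuboid("RGB", r = box[[1]], g = box[[2]], b = box[[3]],
                       label = class_names[i], display_color = palette[[i]])
    }
  })
  threshold_set(cuboids)
}
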