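#' Read and write threshold configurations
#'
#' Threshold sets are serialized as a small YAML document: the color space,
#' an optional overlay background color (hex), and one entry per cuboid with
#' its label, the three `[min, max]` ranges (keys `h`/`s`/`v` or `r`/`g`/`b`)
#' and a hex display color. Reading a file written by
#' [write_threshold_config()] reproduces the threshold set exactly.
#'
#' @param path file path.
#' @return [read_threshold_config()] returns a [threshold_set()];
#'   [write_threshold_config()] returns `path` invisibly.
#' @examples
#' ts <- threshold_set(
#'   threshold_cuboid("HSV", h = c(300, 385), s = c(30, 255), v = c(60, 255),
#'                    label = "muscle", display_color = c(255, 0, 0)))
#' f <- tempfile(fileext = ".yaml")
#' write_threshold_config(ts, f)
#' identical(read_threshold_config(f), ts)
#' @name threshold_config
NULL

#' @rdname threshold_config
#' @param ts a [threshold_set()].
#' @export
write_threshold_config <- function(ts, path) {
  stopifnot(inherits(ts, "threshold_set"))
  doc <- list(
    space = ts$space,
    background_color = .rgb_to_hex(ts$background_color),
    cuboids = lapply(ts$cuboids, function(cb) {
      c(list(label = cb$label),
        lapply(cb$ranges, as.numeric),
        list(display_color = .rgb_to_hex(cb$display_color)))
    })
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname threshold_config
#' @export
read_threshold_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$space) || is.null(doc$cuboids)) {
    stop("threshold config needs 'space' and 'cuboids' entries", call. = FALSE)
  }
  axes <- if (toupper(doc$space) == "HSV") c("h", "s", "v") else c("r", "g", "b")
  cuboids <- lapply(doc$cuboids, function(e) {
    args <- lapply(e[axes], as.numeric)
    do.call(threshold_cuboid,
            c(list(colorspace = toupper(doc$space)), args,
              list(label = e$label,
                   display_color = .hex_to_rgb(e$display_color))))
  })
  bg <- if (is.null(doc$background_color)) c(255, 255, 0) else
    .hex_to_rgb(doc$background_color)
  threshold_set(cuboids, background_color = bg)
}

.rgb_to_hex <- function(col) {
  sprintf("#%02X%02X%02X", round(col[1]), round(col[2]), round(col[3]))
}

.hex_to_rgb <- function(hex) {
  m <- grDevices::col2rgb(hex)
  as.numeric(m[, 1])
}
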