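#' Read a raster image into an 8-bit RGB array
#'
#' Decodes PNG, TIFF, JPEG, BMP or GIF files into an `h x w x 3` integer
#' array with channel values in `[0, 255]`, the universal input of the
#' analysis functions. The format is inferred from the file extension, with
#' a fallback on magic bytes. Grayscale images are promoted to RGB;
#' 16-bit TIFFs are down-converted by rounding `value / 257` to the nearest
#' 8-bit level; an alpha channel, when present, is preserved as an `"alpha"`
#' attribute (a matrix in `[0, 255]`) and fully transparent pixels are
#' excluded from the default ROI downstream. CMYK JPEGs raise an explicit
#' error rather than being converted silently. Animated GIFs decode to their
#' first frame.
#'
#' Reading a JPEG emits a warning: JPEG compression and chroma subsampling
#' perturb pixel colors, and therefore hue, relative to the acquired image.
#'
#' @param path path to the image file.
#' @return `h x w x 3` array with `space = "RGB"` (and possibly `alpha`)
#'   attributes.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  fmt <- .sniff_format(path)
  raw01 <- switch(fmt,
    png = png::readPNG(path),
    tiff = tiff::readTIFF(path),
    jpeg = {
      warning("JPEG is lossy: compression and chroma subsampling perturb ",
              "pixel colors (and hue) relative to the original image",
              call. = FALSE)
      jpeg::readJPEG(path)
    },
    bmp = .read_bmp(path) / 255,
    gif = .read_gif(path) / 255,
    stop("unsupported image format for ", path, call. = FALSE)
  )
  .to_rgb255(raw01, fmt)
}

#' Write an RGB image array to a lossless file
#'
#' Writes PNG or TIFF (chosen by extension) with 8 bits per channel; an
#' `"alpha"` attribute, if present, is written as the alpha channel. The
#' write is bit-exact: reading the file back yields the identical array.
#'
#' @param img `h x w x 3` RGB array, values in `[0, 255]`.
#' @param path destination ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  ext <- tolower(tools::file_ext(path))
  arr <- .clamp255(round(img)) / 255
  alpha <- attr(img, "alpha", exact = TRUE)
  if (!is.null(alpha)) {
    arr <- array(c(arr, .clamp255(round(alpha)) / 255),
                 dim = c(dim(img)[1:2], 4L))
  }
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L, compression = "none")
  } else {
    stop("lossless output must be .png or .tiff, got .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Write the recolored overlay of an extraction result
#'
#' @param result an `extraction_result` from [apply_threshold_set()] (or a
#'   `method_comparison` from [compare_methods()]).
#' @param path destination PNG/TIFF path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(result, path) {
  if (!inherits(result, c("extraction_result", "method_comparison"))) {
    stop("result must come from apply_threshold_set() or compare_methods()",
         call. = FALSE)
  }
  write_image(result$overlay, path)
}

#' Write a binary mask as a 0/255 grayscale PNG
#'
#' Thresholding the written file at any level in (0, 255) recovers the
#' boolean mask exactly.
#'
#' @param mask logical matrix.
#' @param path destination PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' Read a region-of-interest mask from a grayscale image
#'
#' Any pixel with a nonzero value (in any channel) is inside the ROI.
#'
#' @param path image file path.
#' @return Logical matrix.
#' @export
read_roi_mask <- function(path) {
  img <- suppressWarnings(read_image(path))
  img[, , 1] > 0 | img[, , 2] > 0 | img[, , 3] > 0
}

#' Tabulate extraction results across images
#'
#' Builds the long results table written by [write_results()]: one row per
#' (image, cuboid) pair, in input order, with the pixel count, percent of
#' ROI, and the ROI size.
#'
#' @param results a named list of `extraction_result` objects; names are the
#'   image identifiers.
#' @return A `data.frame` with columns `image`, `label`, `pixel_count`,
#'   `percent_area`, `roi_pixel_count`.
#' @export
results_table <- function(results) {
  stopifnot(is.list(results), length(results) > 0)
  ids <- names(results)
  if (is.null(ids)) ids <- as.character(seq_along(results))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(image = ids[i], label = r$labels,
               pixel_count = as.integer(r$counts),
               percent_area = as.numeric(r$percent_area),
               roi_pixel_count = r$roi_pixel_count,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Write / read the results CSV
#'
#' The CSV has a header row and one row per (image, cuboid); percent area is
#' printed with four decimals. Output is deterministic: the same table
#' always produces byte-identical files.
#'
#' @param table data.frame from [results_table()].
#' @param path destination `.csv`.
#' @return `path` (write) or the parsed `data.frame` (read).
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  need <- c("image", "label", "pixel_count", "percent_area", "roi_pixel_count")
  stopifnot(all(need %in% names(table)))
  lines <- c(paste(need, collapse = ","),
             sprintf("%s,%s,%d,%.4f,%d",
                     table$image, table$label,
                     as.integer(table$pixel_count),
                     table$percent_area,
                     as.integer(table$roi_pixel_count)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.sniff_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  by_ext <- switch(ext,
    png = "png", tif = "tiff", tiff = "tiff",
    jpg = "jpeg", jpeg = "jpeg", bmp = "bmp", gif = "gif", NULL)
  magic <- readBin(path, "raw", n = 4L)
  by_magic <- if (length(magic) >= 4) {
    if (identical(magic[1:4], as.raw(c(0x89, 0x50, 0x4E, 0x47)))) "png"
    else if (identical(magic[1:3], as.raw(c(0x47, 0x49, 0x46)))) "gif"
    else if (identical(magic[1:2], as.raw(c(0x42, 0x4D)))) "bmp"
    else if (identical(magic[1:2], as.raw(c(0xFF, 0xD8)))) "jpeg"
    else if (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
             identical(magic[1:2], as.raw(c(0x4D, 0x4D)))) "tiff"
    else NULL
  } else NULL
  fmt <- if (!is.null(by_magic)) by_magic else by_ext
  if (is.null(fmt)) stop("cannot determine image format of ", path,
                         call. = FALSE)
  fmt
}

## normalize decoder output (0-1 doubles, 1-4 channels) to 0-255 RGB + alpha
.to_rgb255 <- function(x, fmt) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  nc <- dim(x)[3]
  if (nc == 4L && fmt == "jpeg") {
    stop("CMYK JPEG input is not supported; convert to RGB first",
         call. = FALSE)
  }
  alpha <- NULL
  if (nc == 1L) {
    rgb <- array(rep(x[, , 1], 3L), dim = c(dim(x)[1:2], 3L))
  } else if (nc == 2L) { # gray + alpha
    rgb <- array(rep(x[, , 1], 3L), dim = c(dim(x)[1:2], 3L))
    alpha <- x[, , 2]
  } else if (nc == 3L) {
    rgb <- x[, , 1:3, drop = FALSE]
  } else if (nc == 4L) {
    rgb <- x[, , 1:3, drop = FALSE]
    alpha <- x[, , 4]
  } else {
    stop("unsupported channel count: ", nc, call. = FALSE)
  }
  out <- round(rgb * 255)
  storage.mode(out) <- "integer"
  dim(out) <- c(dim(x)[1:2], 3L)
  attr(out, "space") <- "RGB"
  if (!is.null(alpha)) {
    a <- round(alpha * 255)
    storage.mode(a) <- "integer"
    attr(out, "alpha") <- a
  }
  out
}
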