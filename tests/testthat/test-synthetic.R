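test_that("generated scenes hit their class areas exactly and reproduce", {
  cls <- list(list(label = "a", color = c(205, 70, 48), fraction = 0.25),
              list(label = "b", color = c(55, 75, 190), fraction = 0.50))
  sc <- synthetic_scene(100, 100, classes = cls, geometry = "wedges", seed = 9)
  gen <- generate_scene(sc)
  expect_identical(sum(gen$labels == 1L), 2500L)
  expect_identical(sum(gen$labels == 2L), 5000L)
  expect_identical(unname(gen$class_counts), c(2500L, 5000L))
  # fixed seed: byte-identical repeat
  gen2 <- generate_scene(sc)
  expect_identical(gen2$image, gen$image)
  expect_identical(gen2$labels, gen$labels)
  # image and label mask agree pixel for pixel on class membership
  expect_identical(dim(gen$image)[1:2], dim(gen$labels))
})

test_that("scene generation leaves the global RNG stream untouched", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(generate_scene(synthetic_scene(32, 32, seed = 5)))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("zero jitter yields exactly classes + 1 distinct colors", {
  gen <- generate_scene(synthetic_scene(64, 64, jitter_sv = 0, seed = 2))
  key <- gen$image[, , 1] * 65536L + gen$image[, , 2] * 256L + gen$image[, , 3]
  expect_identical(length(unique(as.vector(key))), 3L) # 2 classes + background
})

test_that("infeasible area fractions are rejected", {
  cls <- list(list(label = "a", color = c(1, 2, 3), fraction = 0.7),
              list(label = "b", color = c(4, 5, 6), fraction = 0.5))
  expect_error(synthetic_scene(10, 10, classes = cls), "sum")
  expect_error(synthetic_scene(10, 10,
    classes = list(list(label = "a", color = c(1, 2, 3), fraction = 0))),
    "fractions")
})

test_that("thickness transform moves only S and V, as hand-computed", {
  # t = 1.5 on a pixel with S = 100, V = 200: S' = 150, V' = 133, H fixed
  px <- hsv_to_rgb(c(30, 100, 200))
  img <- array(as.integer(px), dim = c(1, 1, 3))
  attr(img, "space") <- "RGB"
  out <- apply_thickness(img, 1.5)
  hsv <- rgb_to_hsv(as.vector(out))
  expect_equal(unname(hsv["S"]), 150, tolerance = 0.01)
  expect_equal(unname(hsv["V"]), 200 / 1.5, tolerance = 0.51) # rounds to 133
  expect_equal(unname(hsv["H"]), 30, tolerance = 0.5)

  # t = 1 is the identity up to rounding
  gen <- tiny_scene(48, seed = 3)
  same <- apply_thickness(gen$image, 1)
  expect_lte(max(abs(same - gen$image)), 1L)

  # hue preserved exactly in float, for any t
  hsv_in <- convert_image(gen$image, "HSV")
  for (t in c(0.7, 1.3, 2)) {
    s2 <- hsvstain:::.clamp255(hsv_in[, , 2] * t)
    v2 <- hsvstain:::.clamp255(hsv_in[, , 3] / t)
    arr <- array(c(hsv_in[, , 1], s2, v2), dim = dim(hsv_in))
    back <- rgb_to_hsv(hsv_to_rgb(arr, round = FALSE))
    expect_lt(max(abs(back[, , 1] - hsv_in[, , 1])), 1e-9)
  }
})

test_that("saturation clamps at 255 under strong thickening", {
  px <- hsv_to_rgb(c(120, 200, 240))
  img <- array(as.integer(px), dim = c(1, 1, 3))
  attr(img, "space") <- "RGB"
  hsv <- rgb_to_hsv(as.vector(apply_thickness(img, 2)))
  expect_equal(unname(hsv["S"]), 255)
  expect_equal(unname(hsv["V"]), 120, tolerance = 0.51)
})

test_that("folds are thickness transforms confined to the region", {
  gen <- tiny_scene(64, seed = 7)
  region <- matrix(FALSE, 64, 64)
  region[20:40, 10:50] <- TRUE
  folded <- apply_fold(gen$image, region, layers = 2L)
  ref <- apply_thickness(gen$image, 2)
  for (k in 1:3) {
    expect_identical(folded[, , k][region], ref[, , k][region])
    expect_identical(folded[, , k][!region], gen$image[, , k][!region])
  }
  # hue inside the fold equals hue outside for the same tissue class
  hsv_f <- convert_image(folded, "HSV")
  hsv_o <- convert_image(gen$image, "HSV")
  musc <- gen$labels == 1L
  h_in <- hsv_f[, , 1][musc & region]
  h_out <- hsv_o[, , 1][musc & !region]
  expect_lt(abs(stats::median(h_in) - stats::median(h_out)), 1.5)

  # polygon regions are rasterized; out-of-image polygons rejected
  tri <- cbind(c(5, 60, 30), c(5, 5, 60))
  expect_silent(apply_fold(gen$image, tri, layers = 3L))
  expect_error(apply_fold(gen$image, cbind(c(-5, 60, 30), c(5, 5, 60))),
               "outside")
  expect_error(apply_fold(gen$image, region, layers = 4L), "layers")
})

test_that("polygon rasterization matches a half-plane count", {
  sq <- cbind(c(3, 10, 10, 3), c(3, 3, 10, 10))
  m <- polygon_mask(sq, width = 12, height = 12)
  expect_identical(sum(m), 7L * 7L) # pixel centers strictly inside + edges
  expect_true(m[5, 5])
  expect_false(m[1, 1])
})

test_that("defocus ramp is identity at zero and conserves intensity", {
  gen <- tiny_scene(48, seed = 11)
  expect_identical(apply_defocus(gen$image, 0), gen$image)
  # constant image unchanged by any blur
  flat <- array(137L, dim = c(24, 24, 3))
  attr(flat, "space") <- "RGB"
  expect_lte(max(abs(apply_defocus(flat, 4) - 137L)), 1L)
  # normalized kernels: total intensity conserved within boundary effects
  blurred <- apply_defocus(gen$image, 3)
  rel <- abs(sum(as.numeric(blurred)) - sum(as.numeric(gen$image))) /
    sum(as.numeric(gen$image))
  expect_lt(rel, 0.01)
  # top rows (radius ~ 0) are untouched, bottom rows are smoothed
  expect_identical(blurred[1, , ], gen$image[1, , ])
  bottom_var <- stats::var(as.numeric(blurred[48, , 1]))
  expect_lt(bottom_var, stats::var(as.numeric(gen$image[48, , 1])))
})

test_that("area-average downsampling has the stated geometry and mean", {
  big <- array(60L, dim = c(3000, 40, 3)) # tall-thin stand-in for geometry
  expect_identical(dim(downsample_image(big, 16))[1], 188L)
  # 2x2 uniform at k = 2 collapses to the same color
  u <- array(c(7L, 7L, 7L, 7L, 8L, 8L, 8L, 8L, 9L, 9L, 9L, 9L),
             dim = c(2, 2, 3))
  expect_identical(as.vector(downsample_image(u, 2)), c(7L, 8L, 9L))
  # mean preserved exactly for divisible dims (unrounded path)
  img <- random_rgb_image(24, 32, seed = 19)
  small <- downsample_image(img, 4, round = FALSE)
  expect_equal(mean(small), mean(img))
  expect_error(downsample_image(img, 64), "smaller")
})

test_that("scene artifacts write to disk with a faithful truth table", {
  gen <- tiny_scene(32, seed = 1)
  dir <- tempfile()
  paths <- write_scene(gen, dir)
  expect_true(all(file.exists(paths)))
  truth <- utils::read.csv(paths["truth"])
  expect_identical(truth$pixels[truth$label == "muscle"],
                   unname(gen$class_counts["muscle"]))
  labs <- round(png::readPNG(paths["labels"]) * 255)
  expect_identical(unname(labs), unname(gen$labels + 0))
})
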