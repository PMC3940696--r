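make_cuboid_rgb <- function() {
  threshold_cuboid("RGB", r = c(180, 240), g = c(0, 50), b = c(160, 200),
                   label = "purple", display_color = c(255, 0, 255))
}

test_that("single-pixel membership requires all three channel conditions", {
  cb <- make_cuboid_rgb()
  expect_true(pixel_in_cuboid(c(200, 30, 180), cb))
  expect_false(pixel_in_cuboid(c(200, 60, 180), cb)) # G violates [0, 50]
  expect_false(pixel_in_cuboid(c(170, 30, 180), cb))
  expect_false(pixel_in_cuboid(c(200, 30, 210), cb))
  # closed intervals: boundary values are positive
  expect_true(pixel_in_cuboid(c(180, 50, 200), cb))
  expect_true(pixel_in_cuboid(c(240, 0, 160), cb))
})

test_that("hue-wrap intervals match the explicit two-interval reading", {
  cb <- threshold_cuboid("HSV", h = c(300, 385), s = c(0, 255), v = c(0, 255),
                         label = "red_wrap")
  for (h in 0:360) {
    expected <- (h >= 300 & h <= 360) | (h >= 0 & h <= 25)
    expect_identical(pixel_in_cuboid(c(h, 100, 100), cb), expected)
  }
  expect_true(pixel_in_cuboid(c(10, 100, 100), cb)) # 10 + 360 = 370 in [300, 385]
  # space mismatch is a usage error
  expect_error(pixel_in_cuboid(c(10, 10, 10), cb, space = "RGB"), "space")
})

test_that("engine counts equal the naive per-pixel oracle on small images", {
  # cuboids chosen to partially overlap so exclusive != independent
  ts_rgb <- threshold_set(
    threshold_cuboid("RGB", r = c(0, 130), g = c(0, 255), b = c(0, 255), label = "a"),
    threshold_cuboid("RGB", r = c(100, 255), g = c(0, 200), b = c(50, 255), label = "b"),
    threshold_cuboid("RGB", r = c(60, 180), g = c(60, 180), b = c(0, 120), label = "c"))
  ts_hsv <- threshold_set(
    threshold_cuboid("HSV", h = c(300, 385), s = c(40, 255), v = c(50, 255), label = "a"),
    threshold_cuboid("HSV", h = c(0, 140), s = c(0, 255), v = c(0, 255), label = "b"),
    threshold_cuboid("HSV", h = c(100, 260), s = c(0, 200), v = c(80, 255), label = "c"))
  for (seed in 1:3) {
    img <- random_rgb_image(17, 23, seed = seed)
    set.seed(seed + 100)
    roi <- matrix(stats::runif(17 * 23) < 0.8, 17, 23)
    roi[1, 1] <- TRUE

    res <- apply_threshold_set(img, ts_rgb, roi = roi)
    want <- oracle_counts(img, ts_rgb, roi)
    expect_identical(unname(res$counts_independent), want$independent)
    expect_identical(unname(res$counts_exclusive), want$exclusive)

    hsv <- convert_image(img, "HSV")
    res_h <- apply_threshold_set(hsv, ts_hsv, roi = roi)
    want_h <- oracle_counts(hsv, ts_hsv, roi)
    expect_identical(unname(res_h$counts_independent), want_h$independent)
    expect_identical(unname(res_h$counts_exclusive), want_h$exclusive)
  }
})

test_that("percent area, conservation and ROI restriction hold", {
  img <- random_rgb_image(32, 32, seed = 9)
  ts <- threshold_set(
    threshold_cuboid("RGB", r = c(0, 127), g = c(0, 255), b = c(0, 255), label = "lo"),
    threshold_cuboid("RGB", r = c(64, 255), g = c(0, 255), b = c(0, 255), label = "hi"))
  res <- apply_threshold_set(img, ts)
  # exclusive partition of the ROI
  expect_identical(sum(res$counts_exclusive) + res$unassigned,
                   res$roi_pixel_count)
  expect_equal(unname(res$percent_area),
               unname(100 * res$counts / res$roi_pixel_count))
  expect_true(all(res$percent_area >= 0 & res$percent_area <= 100))
  expect_identical(unname(res$percent_area == 0), unname(res$counts == 0L))

  # restricting to an ROI equals masking full-image results
  roi <- matrix(FALSE, 32, 32); roi[5:20, 10:25] <- TRUE
  res_roi <- apply_threshold_set(img, ts, roi = roi)
  full <- apply_threshold_set(img, ts)
  for (lab in res$labels) {
    expect_identical(res_roi$masks_independent[[lab]],
                     full$masks_independent[[lab]] & roi)
    expect_identical(sum(res_roi$masks_independent[[lab]]),
                     sum(full$masks_independent[[lab]] & roi))
  }
  expect_error(apply_threshold_set(img, ts, roi = matrix(FALSE, 32, 32)),
               "empty")
  expect_error(apply_threshold_set(img, ts, roi = matrix(TRUE, 3, 3)),
               "dimensions")
  expect_error(apply_threshold_set(convert_image(img, "HSV"), ts), "space")
})

test_that("enlarging a cuboid interval never decreases its count", {
  img <- random_rgb_image(24, 24, seed = 4)
  base <- c(60, 180)
  prev <- -1L
  for (grow in c(0, 20, 40, 80, 120)) {
    cb <- threshold_cuboid("RGB", r = base + c(-1, 1) * grow * 0.5,
                           g = c(0, 255), b = c(0, 255), label = "x")
    n <- apply_threshold_set(img, threshold_set(cb))$counts[["x"]]
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("trivial whole-image selections behave as stated", {
  img <- array(rep(c(200L, 30L, 180L), each = 9), dim = c(3, 3, 3))
  attr(img, "space") <- "RGB"
  ts <- threshold_set(make_cuboid_rgb())
  res <- apply_threshold_set(img, ts)
  expect_identical(res$counts[["purple"]], 9L)
  expect_equal(res$percent_area[["purple"]], 100)
  # all positive pixels recolored to the display color
  expect_true(all(res$overlay[, , 1] == 255 & res$overlay[, , 3] == 255))

  miss <- threshold_set(threshold_cuboid("RGB", r = c(0, 10), g = c(0, 10),
                                         b = c(0, 10), label = "none"))
  res2 <- apply_threshold_set(img, miss)
  expect_identical(res2$counts[["none"]], 0L)
  expect_equal(res2$percent_area[["none"]], 0)
  # overlay is pure background everywhere
  expect_true(all(res2$overlay[, , 1] == 255 & res2$overlay[, , 2] == 255 &
                  res2$overlay[, , 3] == 0))
})

test_that("overlapping cuboids: first-match overlay, both count modes reported", {
  img <- array(c(100L, 100L, 100L), dim = c(1, 1, 3))
  attr(img, "space") <- "RGB"
  both <- threshold_set(
    threshold_cuboid("RGB", r = c(0, 255), g = c(0, 255), b = c(0, 255),
                     label = "first", display_color = c(1, 2, 3)),
    threshold_cuboid("RGB", r = c(50, 150), g = c(50, 150), b = c(50, 150),
                     label = "second", display_color = c(9, 9, 9)))
  res <- apply_threshold_set(img, both)
  expect_identical(unname(res$counts_independent), c(1L, 1L))
  expect_identical(unname(res$counts_exclusive), c(1L, 0L))
  expect_identical(as.vector(res$overlay), c(1L, 2L, 3L)) # earlier cuboid wins
  ind <- apply_threshold_set(img, both, mode = "independent")
  expect_identical(unname(ind$counts), c(1L, 1L))
})

test_that("three-class extraction matches generator ground truth", {
  gen <- tiny_scene(128, seed = 2, classes = trichrome_classes(necrotic = TRUE))
  ts <- fit_class_thresholds(gen$image, gen$labels, "HSV",
                             names(gen$class_counts))
  res <- extract_three_colors(convert_image(gen$image, "HSV"), ts)
  n <- prod(dim(gen$labels))
  for (k in seq_along(res$labels)) {
    truth <- gen$class_counts[[res$labels[k]]]
    # boundary-free scene: counts match truth within a small tolerance
    expect_lt(abs(res$counts[[k]] - truth) / truth, 0.02)
  }
  expect_error(extract_three_colors(convert_image(gen$image, "HSV"),
                                    threshold_set(ts$cuboids[1:2])),
               "3 cuboids")
})

test_that("method comparison reports agreement and disagreement masks", {
  img <- random_rgb_image(20, 20, seed = 3)
  ts_hsv <- threshold_set(threshold_cuboid("HSV", h = c(0, 360), s = c(0, 255),
                                           v = c(0, 255), label = "all"))
  ts_rgb <- threshold_set(threshold_cuboid("RGB", r = c(0, 255), g = c(0, 255),
                                           b = c(0, 255), label = "all"))
  cmp <- compare_methods(img, ts_hsv, ts_rgb)
  # identical effective selections: no one-sided pixels
  expect_identical(sum(cmp$rgb_only), 0L)
  expect_identical(sum(cmp$hsv_only), 0L)
  expect_identical(sum(cmp$agreement), 400L)

  # RGB selecting a strict superset: hsv_only empty, rgb_only nonempty
  ts_hsv2 <- threshold_set(threshold_cuboid("HSV", h = c(0, 360), s = c(0, 255),
                                            v = c(100, 255), label = "bright"))
  cmp2 <- compare_methods(img, ts_hsv2, ts_rgb)
  expect_identical(sum(cmp2$hsv_only), 0L)
  expect_gt(sum(cmp2$rgb_only), 0L)
  # overlay uses yellow / green on agreement and rgb-only pixels
  yel <- cmp2$agreement
  expect_true(all(cmp2$overlay[, , 1][yel] == 255 &
                  cmp2$overlay[, , 2][yel] == 255 &
                  cmp2$overlay[, , 3][yel] == 0))
  grn <- cmp2$rgb_only
  expect_true(all(cmp2$overlay[, , 1][grn] == 0 &
                  cmp2$overlay[, , 2][grn] == 255))
  expect_error(compare_methods(img, ts_rgb, ts_rgb), "HSV")
})

test_that("cuboid and set constructors validate their invariants", {
  expect_error(threshold_cuboid("HSV", h = c(10, 5), s = c(0, 255),
                                v = c(0, 255)), "min > max")
  expect_error(threshold_cuboid("HSV", h = c(0, 730), s = c(0, 255),
                                v = c(0, 255)), "outside")
  expect_error(threshold_cuboid("RGB", r = c(0, 300), g = c(0, 255),
                                b = c(0, 255)), "outside")
  expect_error(threshold_cuboid("RGB", r = c(0, 255), g = c(0, 255)), "ranges")
  cb_h <- threshold_cuboid("HSV", h = c(0, 360), s = c(0, 255), v = c(0, 255))
  cb_r <- threshold_cuboid("RGB", r = c(0, 255), g = c(0, 255), b = c(0, 255))
  expect_error(threshold_set(cb_h, cb_r), "one color space")
  expect_error(threshold_set(), "1 to 3")
  expect_error(threshold_set(cb_h, cb_h, cb_h, cb_h), "1 to 3")
})
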