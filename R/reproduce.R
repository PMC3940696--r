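#' Run a synthetic robustness experiment (HSV vs RGB)
#'
#' Replays one of the sectioning-artifact experiments on ground-truthed
#' synthetic scenes: a reference scene is generated, threshold sets for both
#' methods are fit once on the unperturbed reference
#' ([fit_class_thresholds()]) and then held fixed while the perturbed
#' conditions are analyzed — the protocol of tuning on a single image and
#' leaving parameters constant.
#'
#' Experiments and their default conditions:
#' \describe{
#'   \item{thickness}{thickness factors `t = 0.8, 1.0, 1.2` (reference
#'     `t = 1`); S scales by `t`, V by `1/t`, hue untouched.}
#'   \item{downsample}{area-average reduction by linear factors
#'     `k = 1, 2, 4, 8, 16` (reference `k = 1`).}
#'   \item{magnification}{sampling-density change over a fixed field of
#'     view, modeled as area-average resampling at factors `m = 1, 2, 4`.}
#'   \item{fold}{a horizontal tissue band folded to 2 and 3 layers;
#'     measurements are restricted to the folded band and compared with the
#'     same band unfolded.}
#'   \item{defocus}{linear tilt-gradient blur with maximum sigma
#'     `0, 2, 4, 8` pixels (reference 0).}
#' }
#'
#' Percent areas in each condition are normalized to the reference condition
#' (`normalized = 100 * percent / percent_reference`), and each method's
#' maximum relative deviation from its reference is summarized.
#'
#' @param experiment one of `"thickness"`, `"downsample"`,
#'   `"magnification"`, `"fold"`, `"defocus"`.
#' @param seeds integer vector of scene seeds; one scene per seed.
#' @param size linear scene size in pixels (square scenes).
#' @param classes class list for [synthetic_scene()].
#' @param conditions optional numeric vector overriding the default
#'   condition grid (thickness factors, downsample factors, fold layers, or
#'   blur radii).
#' @param jitter_sv S/V jitter sigma passed to the scene (default 10).
#' @return A `robustness_report`: `$table` (long data.frame with columns
#'   seed, condition, method, class, percent_area, percent_reference,
#'   normalized), `$summary` (per-method max relative deviation, percent),
#'   `$thresholds` (the fitted sets of the first seed), `$experiment`.
#' @export
run_robustness_experiment <- function(experiment = c("thickness", "downsample",
                                                     "magnification", "fold",
                                                     "defocus"),
                                      seeds = 1L, size = 384L,
                                      classes = trichrome_classes(),
                                      conditions = NULL, jitter_sv = 10) {
  experiment <- match.arg(experiment)
  conditions <- if (!is.null(conditions)) conditions else switch(experiment,
    thickness = c(0.8, 1.0, 1.2),
    downsample = c(1, 2, 4, 8, 16),
    magnification = c(1, 2, 4),
    fold = c(1, 2, 3),       # 1 = unfolded reference
    defocus = c(0, 2, 4, 8)
  )
  ref_cond <- switch(experiment, thickness = 1.0, downsample = 1,
                     magnification = 1, fold = 1, defocus = 0)
  if (!ref_cond %in% conditions) conditions <- c(ref_cond, conditions)

  rows <- list()
  thresholds1 <- NULL
  for (sd in seeds) {
    gen <- generate_scene(synthetic_scene(size, size, classes = classes,
                                          jitter_sv = jitter_sv, seed = sd))
    names_k <- names(gen$class_counts)
    ts_hsv <- fit_class_thresholds(gen$image, gen$labels, "HSV", names_k)
    ts_rgb <- fit_class_thresholds(gen$image, gen$labels, "RGB", names_k)
    if (is.null(thresholds1)) thresholds1 <- list(hsv = ts_hsv, rgb = ts_rgb)

    fold_roi <- NULL
    if (experiment == "fold") {
      h <- size
      fold_roi <- matrix(FALSE, h, size)
      fold_roi[floor(h * 0.40):ceiling(h * 0.58), ] <- TRUE
    }

    measure <- function(img, roi) {
      hsv <- apply_threshold_set(convert_image(img, "HSV"), ts_hsv, roi = roi)
      rgb <- apply_threshold_set(img, ts_rgb, roi = roi)
      list(HSV = hsv$percent_area, RGB = rgb$percent_area)
    }

    per_cond <- lapply(conditions, function(cv) {
      img <- switch(experiment,
        thickness = apply_thickness(gen$image, cv),
        downsample = downsample_image(gen$image, cv),
        magnification = downsample_image(gen$image, cv),
        fold = if (cv == 1) gen$image else
          apply_fold(gen$image, fold_roi, layers = as.integer(cv)),
        defocus = apply_defocus(gen$image, cv)
      )
      roi <- if (experiment == "fold") fold_roi else NULL
      if (experiment %in% c("downsample", "magnification") && cv > 1) {
        roi <- NULL # downsampled image has its own full-frame ROI
      }
      measure(img, roi)
    })
    names(per_cond) <- as.character(conditions)
    ref <- per_cond[[as.character(ref_cond)]]

    for (ci in seq_along(conditions)) {
      for (m in c("HSV", "RGB")) {
        pct <- per_cond[[ci]][[m]]
        rows[[length(rows) + 1L]] <- data.frame(
          seed = sd, condition = conditions[ci], method = m,
          class = names_k,
          percent_area = as.numeric(pct),
          percent_reference = as.numeric(ref[[m]]),
          normalized = 100 * as.numeric(pct) / as.numeric(ref[[m]]),
          row.names = NULL)
      }
    }
  }
  table <- do.call(rbind, rows)
  dev <- abs(table$normalized - 100)
  summary <- do.call(rbind, lapply(c("HSV", "RGB"), function(m) {
    d <- dev[table$method == m & is.finite(dev)]
    data.frame(method = m, max_rel_dev = max(d), row.names = NULL)
  }))
  structure(list(experiment = experiment, table = table, summary = summary,
                 thresholds = thresholds1, seeds = seeds, size = size,
                 conditions = conditions),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Robustness experiment:", x$experiment,
      sprintf("(%dx%d scene, %d seed%s)\n", x$size, x$size,
              length(x$seeds), if (length(x$seeds) > 1) "s" else ""))
  cat("Max relative deviation from reference condition (%):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
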