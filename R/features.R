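## Regional grayscale features of the vertebral ROI: the five-region
## partition, sigma-threshold clipping, and the 23-element feature vector fed
## to the BMD regressor.

#' Partition a vertebral ROI into five named regions
#'
#' Lays a 3x3 grid over the ROI (cell boundaries at `floor(i * n / 3)`) and
#' groups the cells into five regions: `upper` (entire top row of cells),
#' `lower` (entire bottom row), and `left`, `central`, `right` (the three
#' middle-row cells). The masks are pairwise disjoint and cover every ROI
#' pixel.
#'
#' @param roi numeric matrix of at least 3x3.
#' @return An object of class `region_partition`: a named list of five
#'   logical masks the shape of `roi`.
#' @examples
#' p <- partition_regions(matrix(0, 9, 9))
#' sum(p$central)  # 9 pixels
#' @export
partition_regions <- function(roi) {
  check_raster(roi, "roi")
  R <- nrow(roi); C <- ncol(roi)
  if (R < 3L || C < 3L) abort("`roi` must be at least 3x3.")
  rb <- c(0L, floor(R / 3), floor(2 * R / 3), R)
  cb <- c(0L, floor(C / 3), floor(2 * C / 3), C)
  band <- function(b, i, n) {
    v <- logical(n)
    v[(b[i] + 1L):b[i + 1L]] <- TRUE
    v
  }
  rows <- lapply(1:3, band, b = rb, n = R)
  cols <- lapply(1:3, band, b = cb, n = C)
  m <- function(ri, ci) outer(rows[[ri]], cols[[ci]], `&`)
  all_cols <- rep(TRUE, C)
  structure(
    list(
      upper = outer(rows[[1]], all_cols, `&`),
      lower = outer(rows[[3]], all_cols, `&`),
      left = m(2, 1),
      central = m(2, 2),
      right = m(2, 3)
    ),
    class = "region_partition"
  )
}

#' Threshold specification for grayscale clipping
#'
#' Builds the clipping interval `[A1, A2]` around a region's mean grayscale,
#' expressed in multiples of its standard deviation:
#' Set 1 is `[mu - sigma, mu + 1.96 sigma]`, Set 2 is
#' `[mu - 1.96 sigma, mu + 1.96 sigma]`, and Set 3 is
#' `[mu - 1.96 sigma, mu + sigma]`.
#'
#' @param mu region mean grayscale.
#' @param sigma region grayscale standard deviation (>= 0).
#' @param set_id 1, 2 or 3.
#' @return An object of class `threshold_spec` with fields `mu`, `sigma`,
#'   `set_id`, `A1`, `A2`.
#' @examples
#' threshold_spec(100, 10, set_id = 2)
#' @export
threshold_spec <- function(mu, sigma, set_id) {
  check_scalar(mu, "mu")
  check_scalar(sigma, "sigma", lo = 0)
  if (!set_id %in% 1:3) abort("`set_id` must be 1, 2 or 3.")
  lo_mult <- c(1, 1.96, 1.96)[set_id]
  hi_mult <- c(1.96, 1.96, 1)[set_id]
  structure(
    list(mu = mu, sigma = sigma, set_id = as.integer(set_id),
         A1 = mu - lo_mult * sigma, A2 = mu + hi_mult * sigma),
    class = "threshold_spec"
  )
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec set %d> [A1, A2] = [%.4g, %.4g] (mu %.4g, sigma %.4g)\n",
              x$set_id, x$A1, x$A2, x$mu, x$sigma))
  invisible(x)
}

#' Clip grayscale values to a threshold interval
#'
#' Values below `A1` become `A1`, values above `A2` become `A2`, all others
#' pass through unchanged. Idempotent.
#'
#' @param region_pixels numeric vector of grayscale values (non-empty).
#' @param spec a [threshold_spec()].
#' @return The clipped values, same length.
#' @examples
#' clip_to_threshold(c(75, 100, 130), threshold_spec(100, 10, 2))
#' @export
clip_to_threshold <- function(region_pixels, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (length(region_pixels) == 0L) abort("empty region.")
  pmin(pmax(region_pixels, spec$A1), spec$A2)
}

#' Mean grayscale of a region
#'
#' @param region_pixels numeric vector (non-empty).
#' @return The arithmetic mean.
#' @export
region_mean <- function(region_pixels) {
  if (length(region_pixels) == 0L) abort("empty region.")
  mean(region_pixels)
}

## Fixed, documented ordering of the 23 features.
feature_names <- function() {
  regions <- c("upper", "lower", "left", "central", "right")
  c(as.vector(t(outer(regions, 1:3, function(r, s) paste0(r, "_set", s)))),
    paste0(regions, "_raw"), "roi_mean", "weight", "area")
}

#' Extract the 23-element feature vector
#'
#' Crops the bone image to the ROI, partitions it into the five named
#' regions, computes each region's grayscale mean and standard deviation,
#' applies the three threshold sets, and assembles the regressor input:
#' 15 threshold-clipped region means (5 regions x 3 sets, region-major in
#' the order upper, lower, left, central, right), the 5 raw region means,
#' the whole-ROI mean, body weight (kg) and vertebral area (cm^2).
#'
#' @param bone_image numeric matrix (the subtracted, bone-dominant image).
#' @param roi_box named vector `c(r0, r1, c0, c1)` of the ROI bounding box
#'   (1-based, inclusive), lying within the image.
#' @param weight body weight in kg (> 0).
#' @param area vertebral bone area in cm^2 (> 0).
#' @return A named numeric vector of length 23.
#' @examples
#' img <- matrix(runif(64 * 64), 64, 64)
#' f <- extract_features(img, c(r0 = 10, r1 = 50, c0 = 15, c1 = 45),
#'                       weight = 60, area = 14)
#' length(f)
#' @export
extract_features <- function(bone_image, roi_box, weight, area) {
  check_raster(bone_image, "bone_image")
  check_scalar(weight, "weight", lo = 0, strict = TRUE)
  check_scalar(area, "area", lo = 0, strict = TRUE)
  rb <- as.numeric(roi_box[c("r0", "r1", "c0", "c1")])
  if (any(is.na(rb)) || rb[1] < 1 || rb[3] < 1 ||
      rb[2] > nrow(bone_image) || rb[4] > ncol(bone_image) ||
      rb[2] - rb[1] < 2 || rb[4] - rb[3] < 2) {
    abort("`roi_box` must name r0/r1/c0/c1, lie within the image and span at least 3x3 pixels.")
  }
  roi <- bone_image[rb[1]:rb[2], rb[3]:rb[4], drop = FALSE]
  part <- partition_regions(roi)
  clipped <- numeric(0)
  raw <- numeric(0)
  for (rg in c("upper", "lower", "left", "central", "right")) {
    px <- roi[part[[rg]]]
    mu <- mean(px)
    sg <- sd(px)
    if (!is.finite(sg)) sg <- 0
    for (s in 1:3) {
      clipped <- c(clipped,
                   region_mean(clip_to_threshold(px, threshold_spec(mu, sg, s))))
    }
    raw <- c(raw, mu)
  }
  out <- c(clipped, raw, mean(roi), weight, area)
  names(out) <- feature_names()
  out
}

#' Build the per-sample feature table for a cohort
#'
#' Data-frame-first wrapper around [extract_features()]: takes a cohort
#' manifest, looks up each sample's bone-dominant image (from an in-memory
#' list keyed by `sample_id`, or from the paths in `image_col`), and returns
#' one feature row per sample.
#'
#' @param manifest a tibble with columns `sample_id`, `weight`, `area`, the
#'   ROI columns `roi_r0`, `roi_r1`, `roi_c0`, `roi_c1`, and optionally
#'   `bmd`.
#' @param images optional named list of matrices keyed by `sample_id`.
#' @param image_col manifest column holding raster paths, used when
#'   `images` is `NULL` (default `"bone_path"`).
#' @return A tibble: `sample_id`, the 21 image features, `weight`, `area`
#'   and `bmd` when present in the manifest.
#' @export
extract_feature_table <- function(manifest, images = NULL,
                                  image_col = "bone_path") {
  stopifnot(is.data.frame(manifest))
  rows <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    img <- if (!is.null(images)) {
      images[[r$sample_id]]
    } else {
      read_raster(r[[image_col]])
    }
    f <- extract_features(
      img,
      c(r0 = r$roi_r0, r1 = r$roi_r1, c0 = r$roi_c0, c1 = r$roi_c1),
      weight = r$weight, area = r$area
    )
    tibble::tibble(sample_id = r$sample_id, !!!as.list(f))
  })
  if ("bmd" %in% names(manifest)) {
    rows$bmd <- manifest$bmd
  }
  rows
}
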