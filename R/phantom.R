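## Synthetic phantom radiographs: smooth soft-tissue backgrounds, vertebra
## templates whose mean attenuation encodes a known BMD, jittered four-fold
## compositing, lossless augmentation, and full sample synthesis.

## Intensity constants of the phantom forward model (normalized grayscale).
## Soft tissue occupies a dimmer band than bone so that the additive
## composition input = clamp(soft + bone, 0, 1) rarely saturates. Each image
## draws its own base level and amplitude: patients differ in soft-tissue
## thickness, so the ROI-averaged soft attenuation must vary between images.
SOFT_LEVEL_RANGE <- c(0.05, 0.22)
SOFT_AMP_RANGE <- c(0.18, 0.33)
## Mean bone attenuation inside the vertebra mask is affine in true BMD:
##   mean = BONE_BASE + BONE_SLOPE * bmd   (bmd in g/cm^2)
BONE_BASE <- 0.08
BONE_SLOPE <- 0.38
## Zero-mean trabecular texture superimposed inside the mask.
TEXTURE_SD <- 0.04

## Bilinear resize of a matrix to `out` x `out` (used to blow low-resolution
## noise grids up into smooth octaves).
bilinear_resize <- function(m, out) {
  n_r <- nrow(m); n_c <- ncol(m)
  ## map output pixel centres onto input pixel-centre coordinates
  r <- (seq_len(out) - 0.5) / out * n_r + 0.5
  c <- (seq_len(out) - 0.5) / out * n_c + 0.5
  r0 <- clamp(floor(r), 1, n_r); r1 <- clamp(r0 + 1, 1, n_r)
  c0 <- clamp(floor(c), 1, n_c); c1 <- clamp(c0 + 1, 1, n_c)
  fr <- r - floor(r); fc <- c - floor(c)
  fr[r < 1] <- 0; fr[r > n_r] <- 1
  fc[c < 1] <- 0; fc[c > n_c] <- 1
  a <- m[r0, c0, drop = FALSE]; b <- m[r0, c1, drop = FALSE]
  d <- m[r1, c0, drop = FALSE]; e <- m[r1, c1, drop = FALSE]
  wfr <- matrix(fr, out, out); wfc <- matrix(fc, out, out, byrow = TRUE)
  (a * (1 - wfr) + d * wfr) * (1 - wfc) + (b * (1 - wfr) + e * wfr) * wfc
}

## Sum of band-limited Gaussian noise octaves, min-max normalized to [0, 1].
noise_octaves <- function(size, n_octaves = 3L, base_res = 4L,
                          persistence = 0.55) {
  acc <- matrix(0, size, size)
  amp <- 1
  res <- base_res
  for (k in seq_len(n_octaves)) {
    g <- matrix(rnorm(res * res), res, res)
    acc <- acc + amp * bilinear_resize(g, size)
    amp <- amp * persistence
    res <- min(res * 2L, size)
  }
  rng <- range(acc)
  if (rng[2] > rng[1]) (acc - rng[1]) / (rng[2] - rng[1]) else acc * 0 + 0.5
}

#' Generate a smooth soft-tissue background
#'
#' Produces one synthetic soft-tissue absorption image: a sum of seeded
#' band-limited noise octaves (smooth, low-frequency inhomogeneity from
#' overlapping organs) plus a lateral intensity gradient, scaled to a
#' per-image base level (drawn from `[0.05, 0.22]`) and amplitude (from
#' `[0.18, 0.33]`) of normalized grayscale — so both the spatial pattern and
#' the overall soft-tissue thickness vary between images. Deterministic
#' per seed.
#'
#' @param size pixels per side (>= 32).
#' @param seed integer seed.
#' @return A `size` x `size` numeric matrix with values in `[0, 1]`.
#' @examples
#' bg <- make_soft_background(64, seed = 7)
#' range(bg)
#' @export
make_soft_background <- function(size, seed) {
  check_scalar(size, "size", lo = 32)
  size <- as.integer(size)
  with_seed(seed, {
    field <- noise_octaves(size, n_octaves = 3L, base_res = 4L)
    ## lateral gradient with random direction and strength
    slope <- runif(1, -0.35, 0.35)
    grad <- matrix(seq(0, 1, length.out = size), size, size, byrow = TRUE)
    field <- field + slope * grad
    rng <- range(field)
    field <- (field - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    level <- runif(1, SOFT_LEVEL_RANGE[1], SOFT_LEVEL_RANGE[2])
    amp <- runif(1, SOFT_AMP_RANGE[1], SOFT_AMP_RANGE[2])
    clamp(level + amp * field)
  })
}

## Rounded-rectangle membership mask centred in an n x n frame.
rounded_rect_mask <- function(size, half_h, half_w, radius) {
  ctr <- (size + 1) / 2
  dr <- abs(row(matrix(0, size, size)) - ctr) - (half_h - radius)
  dc <- abs(col(matrix(0, size, size)) - ctr) - (half_w - radius)
  drp <- pmax(dr, 0); dcp <- pmax(dc, 0)
  sqrt(drp^2 + dcp^2) + pmin(pmax(dr, dc), 0) <= radius
}

#' Generate a vertebra template with BMD-driven trabecular texture
#'
#' Draws a rounded-rectangle vertebral body centred in the frame. The mean
#' intensity inside the mask follows the affine attenuation map
#' `mean = 0.08 + 0.38 * bmd` (normalized grayscale per g/cm^2), on top of
#' which seeded multi-scale zero-mean texture (sd 0.04) emulates trabecular
#' structure. Pixels outside the mask are exactly zero.
#'
#' @param size pixels per side (>= 32).
#' @param bmd true bone mineral density in g/cm^2, strictly inside (0, 2).
#' @param seed integer seed.
#' @return A list with elements `raster` (numeric matrix in `[0, 1]`) and
#'   `mask` (logical matrix).
#' @examples
#' v <- make_vertebra_template(64, bmd = 0.9, seed = 3)
#' mean(v$raster[v$mask])  # ~ 0.08 + 0.38 * 0.9
#' @export
make_vertebra_template <- function(size, bmd, seed) {
  check_scalar(size, "size", lo = 32)
  check_scalar(bmd, "bmd", lo = 0, hi = 2, strict = TRUE)
  size <- as.integer(size)
  mask <- rounded_rect_mask(size,
                            half_h = 0.28 * size,
                            half_w = 0.20 * size,
                            radius = 0.06 * size)
  with_seed(seed, {
    tex <- noise_octaves(size, n_octaves = 3L, base_res = 8L) - 0.5
    tex_in <- tex[mask]
    tex_in <- (tex_in - mean(tex_in)) /
      max(sd(tex_in), .Machine$double.eps) * TEXTURE_SD
    raster <- matrix(0, size, size)
    raster[mask] <- clamp(BONE_BASE + BONE_SLOPE * bmd + tex_in)
    list(raster = raster, mask = mask)
  })
}

#' Rotate a raster by an arbitrary angle
#'
#' Bilinear resampling about the image centre with zero fill outside the
#' source frame. Angles that are multiples of 360 return the input unchanged;
#' multiples of 90 map grid points onto grid points exactly (up to floating
#' point).
#'
#' @param x numeric matrix.
#' @param degrees rotation angle.
#' @return A matrix of the same shape.
#' @export
rotate_raster <- function(x, degrees) {
  check_raster(x)
  check_scalar(degrees, "degrees")
  if (degrees %% 360 == 0) return(x)
  n_r <- nrow(x); n_c <- ncol(x)
  th <- degrees * pi / 180
  ct <- cos(th); st <- sin(th)
  cr <- (n_r + 1) / 2; cc <- (n_c + 1) / 2
  dr <- matrix(seq_len(n_r) - cr, n_r, n_c)
  dc <- matrix(seq_len(n_c) - cc, n_r, n_c, byrow = TRUE)
  ## inverse map: output pixel pulls from source coordinates
  sr <- ct * dr - st * dc + cr
  sc <- st * dr + ct * dc + cc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  out <- numeric(n_r * n_c)
  px <- function(ri, ci) {
    v <- numeric(length(ri))
    ok <- ri >= 1 & ri <= n_r & ci >= 1 & ci <= n_c
    v[ok] <- x[cbind(ri[ok], ci[ok])]
    v
  }
  r0v <- as.vector(r0); c0v <- as.vector(c0)
  frv <- as.vector(fr); fcv <- as.vector(fc)
  out <- px(r0v, c0v) * (1 - frv) * (1 - fcv) +
    px(r0v + 1, c0v) * frv * (1 - fcv) +
    px(r0v, c0v + 1) * (1 - frv) * fcv +
    px(r0v + 1, c0v + 1) * frv * fcv
  matrix(out, n_r, n_c)
}

#' Apply contrast, brightness and tilt jitter to a template
#'
#' Computes `clamp(contrast * template + brightness, 0, 1)` and rotates the
#' result by `tilt` degrees about the image centre with zero fill. Shape is
#' preserved.
#'
#' @param template numeric matrix in `[0, 1]`.
#' @param contrast multiplicative factor (> 0).
#' @param brightness additive offset in normalized grayscale.
#' @param tilt rotation in degrees.
#' @return A matrix of the same shape, values in `[0, 1]`.
#' @examples
#' m <- matrix(0.3, 64, 64)
#' range(jitter_template(m, contrast = 2, brightness = 0, tilt = 0))
#' @export
jitter_template <- function(template, contrast, brightness, tilt) {
  check_raster(template, "template")
  check_scalar(contrast, "contrast", lo = 0, strict = TRUE)
  check_scalar(brightness, "brightness")
  check_scalar(tilt, "tilt")
  rotate_raster(clamp(contrast * template + brightness), tilt)
}

#' Composite four jittered bone templates into one mask
#'
#' The four contrast/brightness/tilt variants of a vertebra template are
#' merged by their pixel-wise mean, clamped to `[0, 1]`. The mean keeps
#' intensities in range without renormalization.
#'
#' @param jittered a list of exactly four numeric matrices of identical shape.
#' @return A matrix of the common shape.
#' @examples
#' m <- matrix(0.2, 32, 32)
#' composite_bone_mask(list(m, m + 0.2, m + 0.4, m + 0.6))[1, 1]
#' @export
composite_bone_mask <- function(jittered) {
  if (!is.list(jittered) || length(jittered) != 4L) {
    abort("`jittered` must be a list of exactly four rasters.")
  }
  for (m in jittered) check_raster(m)
  d <- dim(jittered[[1]])
  if (!all(vapply(jittered, function(m) identical(dim(m), d), logical(1)))) {
    abort("all four rasters must share the same shape.")
  }
  clamp(Reduce(`+`, jittered) / 4)
}

## Exact quarter-turn: out[r, c] = in[n + 1 - c, r] (square matrices only).
rot90_once <- function(x) {
  n <- nrow(x)
  t(x)[, rev(seq_len(n)), drop = FALSE]
}

#' Lossless rotation/flip augmentation
#'
#' Exact pixel remapping by quarter-turn rotations and axis flips; applying
#' the inverse transform restores the input bit-exactly.
#'
#' @param x square numeric matrix.
#' @param rotation one of 0, 90, 180, 270 (degrees).
#' @param flip one of `"none"`, `"horizontal"`, `"vertical"`.
#' @return The remapped matrix.
#' @examples
#' m <- matrix(runif(16), 4, 4)
#' identical(augment_raster(augment_raster(m, 180), 180), m)
#' @export
augment_raster <- function(x, rotation = 0, flip = c("none", "horizontal",
                                                     "vertical")) {
  check_raster(x)
  if (nrow(x) != ncol(x)) abort("`x` must be square.")
  if (!rotation %in% c(0, 90, 180, 270)) {
    abort("`rotation` must be one of 0, 90, 180, 270.")
  }
  flip <- match.arg(flip)
  k <- (rotation / 90) %% 4
  for (i in seq_len(k)) x <- rot90_once(x)
  if (flip == "horizontal") x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
  if (flip == "vertical") x <- x[rev(seq_len(nrow(x))), , drop = FALSE]
  x
}

## Bounding box (r0, r1, c0, c1) of TRUE pixels in a logical mask.
mask_bbox <- function(mask) {
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  c(r0 = rr[1], r1 = rr[2], c0 = cc[1], c1 = cc[2])
}

#' Synthesize one phantom sample
#'
#' Builds one complete training unit: a soft-tissue background, a vertebra
#' template with BMD drawn uniformly from `config$bmd_range`, four jittered
#' template variants merged into a composite bone image, lossless
#' rotation/flip augmentation, and the additive radiograph
#' `input = clamp(soft + bone, 0, 1)` with seeded Gaussian acquisition noise.
#' Body weight and vertebral area covariates follow the linear-Gaussian model
#' `weight = 40 + 25 * bmd + N(0, 4^2)` kg and
#' `area = 10 + 4 * bmd + N(0, 1^2)` cm^2, mirroring the reported positive
#' correlation of both with BMD.
#'
#' @param config a [phantom_config()].
#' @param sample_seed integer; together with `config$seed` it fully determines
#'   the sample.
#' @return An object of class `phantom_sample`: a list with elements
#'   `input_image`, `soft_label`, `bone_truth`, `bone_mask`, `roi`
#'   (named vector r0/r1/c0/c1), `bmd_true`, `weight`, `area`, `sample_id`.
#' @examples
#' s <- synthesize_sample(phantom_config(image_size = 64), sample_seed = 1)
#' s$bmd_true
#' @export
synthesize_sample <- function(config, sample_seed) {
  stopifnot(inherits(config, "phantom_config"))
  check_scalar(sample_seed, "sample_seed")
  seed <- derive_seed(config$seed, sample_seed)
  with_seed(seed, {
    n <- config$image_size
    bmd <- runif(1, config$bmd_range[1], config$bmd_range[2])
    soft_seed <- sample.int(2^31 - 2, 1)
    bone_seed <- sample.int(2^31 - 2, 1)
    soft <- make_soft_background(n, soft_seed)
    vert <- make_vertebra_template(n, bmd, bone_seed)
    jit <- lapply(seq_len(4), function(i) {
      jitter_template(
        vert$raster,
        contrast = runif(1, config$contrast_range[1], config$contrast_range[2]),
        brightness = runif(1, config$brightness_range[1],
                           config$brightness_range[2]),
        tilt = runif(1, config$tilt_range[1], config$tilt_range[2])
      )
    })
    bone <- composite_bone_mask(jit)
    rotation <- sample(c(0, 90, 180, 270), 1)
    flip <- sample(c("none", "horizontal", "vertical"), 1)
    bone <- augment_raster(bone, rotation, flip)
    mask <- augment_raster(vert$mask * 1, rotation, flip) > 0.5
    pre_noise <- clamp(soft + bone)
    input <- clamp(pre_noise + rnorm(n * n, 0, config$noise_sd))
    weight <- 40 + 25 * bmd + rnorm(1, 0, 4)
    area <- 10 + 4 * bmd + rnorm(1, 0, 1)
    structure(
      list(
        input_image = input,
        input_prenoise = pre_noise,
        soft_label = soft,
        bone_truth = bone,
        bone_mask = mask,
        roi = mask_bbox(mask),
        bmd_true = bmd,
        weight = weight,
        area = area,
        sample_id = sprintf("s%06d", as.integer(sample_seed))
      ),
      class = "phantom_sample"
    )
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf(
    "<phantom_sample %s> %dx%d px, BMD %.3f g/cm^2, weight %.1f kg, area %.1f cm^2\n",
    x$sample_id, nrow(x$input_image), ncol(x$input_image),
    x$bmd_true, x$weight, x$area
  ))
  invisible(x)
}

#' Synthesize an in-memory phantom cohort
#'
#' Generates `n` independent phantom samples (sample seeds `1:n`) and the
#' matching manifest tibble. Pure function of `(config, n)`.
#'
#' @param config a [phantom_config()].
#' @param n number of samples (>= 1).
#' @return A list with `samples` (list of `phantom_sample`) and `manifest`
#'   (tibble with sample_id, bmd, weight, area and ROI columns).
#' @examples
#' co <- synthesize_cohort(phantom_config(image_size = 64), n = 3)
#' co$manifest
#' @export
synthesize_cohort <- function(config, n) {
  stopifnot(inherits(config, "phantom_config"))
  check_scalar(n, "n", lo = 1)
  samples <- lapply(seq_len(n), function(i) synthesize_sample(config, i))
  manifest <- purrr::map_dfr(samples, function(s) {
    tibble::tibble(
      sample_id = s$sample_id,
      bmd = s$bmd_true,
      weight = s$weight,
      area = s$area,
      roi_r0 = s$roi[["r0"]], roi_r1 = s$roi[["r1"]],
      roi_c0 = s$roi[["c0"]], roi_c1 = s$roi[["c1"]]
    )
  })
  list(samples = samples, manifest = manifest)
}
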