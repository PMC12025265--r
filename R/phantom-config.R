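#' Configuration for the synthetic phantom generator
#'
#' Bundles every knob of the phantom cohort generator: raster size, jitter
#' ranges used to derive the four bone-template variants, the bone mineral
#' density (BMD) interval the ground truth is drawn from, and the additive
#' noise level of the final radiograph. Defaults reflect a desk-scale cohort;
#' `image_size = 256` mirrors full-size radiograph crops.
#'
#' @param image_size pixels per side of the square rasters (>= 32; must be
#'   divisible by `2^depth` of the U-Net it feeds, 8 for the default depth 3).
#' @param n_soft,n_bone nominal counts of distinct soft-tissue backgrounds and
#'   vertebra templates a full cohort draws from (150 each by default).
#' @param contrast_range multiplicative contrast jitter interval.
#' @param brightness_range additive brightness jitter interval, in normalized
#'   grayscale units.
#' @param tilt_range angular tilt jitter interval, degrees.
#' @param bmd_range interval of true BMD values, g/cm^2; must lie inside
#'   (0, 2).
#' @param noise_sd standard deviation of the additive Gaussian acquisition
#'   noise, in normalized grayscale units.
#' @param seed integer seed; together with a per-sample seed it makes every
#'   sample a pure function of its arguments.
#' @return An object of class `phantom_config` (a validated list).
#' @examples
#' cfg <- phantom_config(image_size = 64, seed = 1)
#' cfg$bmd_range
#' @export
phantom_config <- function(image_size = 128L,
                           n_soft = 150L,
                           n_bone = 150L,
                           contrast_range = c(0.9, 1.1),
                           brightness_range = c(-0.03, 0.03),
                           tilt_range = c(-5, 5),
                           bmd_range = c(0.35, 1.35),
                           noise_sd = 0.02,
                           seed = 1L) {
  check_scalar(image_size, "image_size", lo = 32)
  check_scalar(n_soft, "n_soft", lo = 1)
  check_scalar(n_bone, "n_bone", lo = 1)
  check_scalar(noise_sd, "noise_sd", lo = 0)
  check_scalar(seed, "seed")
  for (nm in c("contrast_range", "brightness_range", "tilt_range",
               "bmd_range")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) ||
        v[1] > v[2]) {
      abort(sprintf("`%s` must be a finite interval c(low, high).", nm))
    }
  }
  if (bmd_range[1] <= 0 || bmd_range[2] >= 2) {
    abort("`bmd_range` must lie strictly inside (0, 2) g/cm^2.")
  }
  if (contrast_range[1] <= 0) {
    abort("`contrast_range` must be strictly positive.")
  }
  structure(
    list(
      image_size = as.integer(image_size),
      n_soft = as.integer(n_soft),
      n_bone = as.integer(n_bone),
      contrast_range = as.numeric(contrast_range),
      brightness_range = as.numeric(brightness_range),
      tilt_range = as.numeric(tilt_range),
      bmd_range = as.numeric(bmd_range),
      noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat(sprintf("  image_size : %d px\n", x$image_size))
  cat(sprintf("  bmd_range  : [%.2f, %.2f] g/cm^2\n",
              x$bmd_range[1], x$bmd_range[2]))
  cat(sprintf("  jitter     : contrast [%.2f, %.2f], brightness [%+.2f, %+.2f], tilt [%+.1f, %+.1f] deg\n",
              x$contrast_range[1], x$contrast_range[2],
              x$brightness_range[1], x$brightness_range[2],
              x$tilt_range[1], x$tilt_range[2]))
  cat(sprintf("  noise_sd   : %.3f, seed %d\n", x$noise_sd, x$seed))
  invisible(x)
}
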