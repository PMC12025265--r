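## Disk round-trip of phantom cohorts: 8-bit PNG / 16-bit TIFF rasters and a
## CSV manifest.

#' Write a grayscale raster to disk
#'
#' Values in `[0, 1]` are written as 8-bit PNG (`.png`) or 16-bit TIFF
#' (`.tif`/`.tiff`), chosen by file extension.
#'
#' @param x numeric matrix in `[0, 1]`.
#' @param path output file path; the directory must exist.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  check_raster(x)
  ext <- tolower(tools::file_ext(path))
  x <- clamp(x)
  if (ext == "png") {
    png::writePNG(x, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, where = path, bits.per.sample = 16L)
  } else {
    abort(sprintf("unsupported raster extension '%s' (use png/tif/tiff).", ext))
  }
  invisible(path)
}

#' Read a grayscale raster from disk
#'
#' @param path a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    abort(sprintf("unsupported raster extension '%s'.", ext))
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Generate a phantom cohort on disk
#'
#' Synthesizes `n` phantom samples, writes the input/soft-label/bone-truth
#' rasters as image files and a manifest CSV
#' (`sample_id,input_path,soft_path,bone_path,bmd,weight,area` plus the ROI
#' bounding-box columns `roi_r0,roi_r1,roi_c0,roi_c1`). The manifest
#' round-trips losslessly through [read_manifest()].
#'
#' @param config a [phantom_config()].
#' @param n number of samples.
#' @param dir output directory (created if missing).
#' @param format `"png"` (8-bit) or `"tiff"` (16-bit).
#' @return The manifest tibble, invisibly; also written to
#'   `file.path(dir, "manifest.csv")`.
#' @examples
#' \donttest{
#' d <- tempfile()
#' m <- generate_cohort(phantom_config(image_size = 64), n = 3, dir = d)
#' nrow(m)
#' }
#' @export
generate_cohort <- function(config, n, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  ext <- if (format == "png") "png" else "tif"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create directory %s", dir))
  co <- synthesize_cohort(config, n)
  paths <- purrr::map_dfr(co$samples, function(s) {
    p <- file.path(dir, sprintf("%s_%%s.%s", s$sample_id, ext))
    ip <- sprintf(p, "input"); sp <- sprintf(p, "soft"); bp <- sprintf(p, "bone")
    write_raster(s$input_image, ip)
    write_raster(s$soft_label, sp)
    write_raster(s$bone_truth, bp)
    tibble::tibble(input_path = ip, soft_path = sp, bone_path = bp)
  })
  manifest <- dplyr::bind_cols(
    co$manifest[, "sample_id"], paths,
    co$manifest[, c("bmd", "weight", "area",
                    "roi_r0", "roi_r1", "roi_c0", "roi_c1")]
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param path a manifest CSV written by [generate_cohort()].
#' @return A tibble with one row per sample.
#' @export
read_manifest <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      input_path = readr::col_character(),
      soft_path = readr::col_character(),
      bone_path = readr::col_character(),
      .default = readr::col_double()
    )
  )
}
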