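## Prediction metrics and the paired before/after-subtraction comparison.

#' Sample Pearson correlation
#'
#' @param x,y numeric vectors of equal length (n >= 2), each with non-zero
#'   variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_r(1:10, 2 * (1:10) + 1)
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2L) abort("need at least two observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("undefined metric: zero variance in `x` or `y`.")
  }
  stats::cor(x, y)
}

#' Mean absolute error
#'
#' @param true,pred numeric vectors of equal length (n >= 1).
#' @return `mean(abs(true - pred))`, in the units of the inputs (g/cm^2 for
#'   BMD predictions).
#' @examples
#' mae(c(1.0, 0.8), c(0.9, 0.9))
#' @export
mae <- function(true, pred) {
  if (length(true) != length(pred)) {
    abort("`true` and `pred` must have equal length.")
  }
  if (length(true) < 1L) abort("need at least one observation.")
  mean(abs(true - pred))
}

#' Evaluation report for a prediction set
#'
#' @param true,pred numeric vectors (true and predicted BMD).
#' @param subset label, e.g. `"train"` or `"validation"`.
#' @param arm label, e.g. `"subtracted"` or `"raw"`.
#' @return A one-row tibble: `arm`, `subset`, `pearson_r`, `r_squared`
#'   (the square of Pearson r), `mae`, `n`.
#' @export
eval_report <- function(true, pred, subset = "validation", arm = "subtracted") {
  r <- pearson_r(true, pred)
  tibble::tibble(
    arm = arm, subset = subset,
    pearson_r = r, r_squared = r^2,
    mae = mae(true, pred), n = length(true)
  )
}

#' Evaluate a tibble of predictions
#'
#' @param predictions a tibble with columns `arm`, `subset`, `bmd_true`,
#'   `bmd_pred`.
#' @return One [eval_report()] row per (arm, subset).
#' @export
evaluate_predictions <- function(predictions) {
  stopifnot(all(c("arm", "subset", "bmd_true", "bmd_pred") %in%
                  names(predictions)))
  predictions |>
    dplyr::group_by(.data$arm, .data$subset) |>
    dplyr::group_modify(function(d, g) {
      eval_report(d$bmd_true, d$bmd_pred)[, c("pearson_r", "r_squared",
                                              "mae", "n")]
    }) |>
    dplyr::ungroup()
}

#' Compare the pipeline with and without soft-tissue subtraction
#'
#' Runs (or summarizes) the paired experiment: identical cohort, identical
#' train/validation split and identical regressor seed, once on the
#' U-Net-subtracted bone images and once on the raw composite radiographs.
#' The contrast isolates the contribution of learned soft-tissue
#' suppression.
#'
#' @param x a [run_config()] (the experiment is executed) or an existing
#'   [run_pipeline()] result.
#' @return An object of class `bmd_comparison`: a list with `reports` (one
#'   row per arm per subset) and `deltas` (validation
#'   `delta_r = r_subtracted - r_raw` and `delta_mae`).
#' @export
compare_pipelines <- function(x) {
  result <- if (inherits(x, "bmd_pipeline_result")) x else run_pipeline(x)
  reports <- result$reports
  val <- reports[reports$subset == "validation", ]
  sub <- val[val$arm == "subtracted", ]
  raw <- val[val$arm == "raw", ]
  structure(
    list(
      reports = reports,
      deltas = tibble::tibble(
        delta_r = sub$pearson_r - raw$pearson_r,
        delta_mae = sub$mae - raw$mae,
        n = sub$n
      )
    ),
    class = "bmd_comparison"
  )
}

#' @export
print.bmd_comparison <- function(x, ...) {
  cat("<bmd_comparison> validation metrics by arm\n")
  print(as.data.frame(x$reports[x$reports$subset == "validation", ]))
  cat(sprintf("delta r (subtracted - raw): %+.3f; delta MAE: %+.4f g/cm^2\n",
              x$deltas$delta_r, x$deltas$delta_mae))
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param comparison a [compare_pipelines()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(comparison, path) {
  stopifnot(inherits(comparison, "bmd_comparison"))
  jsonlite::write_json(
    list(reports = comparison$reports, deltas = comparison$deltas),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
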