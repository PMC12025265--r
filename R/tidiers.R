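## broom-style tidiers for the fitted objects.

#' Tidy the training history of a U-Net
#'
#' @param x a trained `unet_model`.
#' @param ... unused.
#' @return A long tibble `(epoch, loss, mse)` with `loss` in
#'   `{"train", "validation"}`.
#' @exportS3Method generics::tidy
tidy.unet_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), loss = character(),
                          mse = numeric()))
  }
  x$history |>
    tidyr::pivot_longer(c("train_mse", "val_mse"),
                        names_to = "loss", values_to = "mse") |>
    dplyr::mutate(loss = ifelse(.data$loss == "train_mse", "train",
                                "validation"))
}

#' @rdname tidy.unet_model
#' @exportS3Method generics::tidy
tidy.bmd_ann <- function(x, ...) {
  x$history |>
    tidyr::pivot_longer(c("train_mse", "val_mse"),
                        names_to = "loss", values_to = "mse") |>
    dplyr::mutate(loss = ifelse(.data$loss == "train_mse", "train",
                                "validation"))
}

#' One-row summaries of fitted models and pipeline results
#'
#' @param x a `unet_model`, `bmd_ann`, `bmd_pipeline_result` or
#'   `bmd_comparison`.
#' @param ... unused.
#' @return A one-row tibble of headline quantities.
#' @exportS3Method generics::glance
glance.unet_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_parameters = n_parameters(x),
    epochs = if (is.null(h)) 0L else nrow(h),
    train_mse = if (is.null(h)) NA_real_ else h$train_mse[nrow(h)],
    val_mse = if (is.null(h)) NA_real_ else h$val_mse[nrow(h)]
  )
}

#' @rdname glance.unet_model
#' @exportS3Method generics::glance
glance.bmd_ann <- function(x, ...) {
  tibble::tibble(
    n_parameters = n_parameters(x),
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    val_mse = min(x$history$val_mse)
  )
}

#' @rdname tidy.unet_model
#' @exportS3Method generics::tidy
tidy.bmd_pipeline_result <- function(x, ...) x$reports

#' @rdname glance.unet_model
#' @exportS3Method generics::glance
glance.bmd_pipeline_result <- function(x, ...) {
  compare_pipelines(x)$deltas
}

#' @rdname tidy.unet_model
#' @exportS3Method generics::tidy
tidy.bmd_comparison <- function(x, ...) x$reports

#' @rdname glance.unet_model
#' @exportS3Method generics::glance
glance.bmd_comparison <- function(x, ...) x$deltas

#' Per-sample predictions of a pipeline run
#'
#' @param x a `bmd_pipeline_result`.
#' @param ... unused.
#' @return The predictions tibble with residuals added.
#' @exportS3Method generics::augment
augment.bmd_pipeline_result <- function(x, ...) {
  dplyr::mutate(x$predictions, residual = .data$bmd_pred - .data$bmd_true)
}
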