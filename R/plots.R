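## ggplot2 graphics for phantoms, training curves and prediction scatter.

#' Plot a grayscale raster
#'
#' @param x numeric matrix in `[0, 1]`.
#' @param title optional plot title.
#' @return A ggplot object (raster heat map, radiographic gray palette).
#' @export
plot_raster <- function(x, title = NULL) {
  check_raster(x)
  df <- tidyr::expand_grid(row = seq_len(nrow(x)), col = seq_len(ncol(x)))
  df$value <- x[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "gray") +
    ggplot2::theme_minimal()
}

#' Panel view of one phantom sample
#'
#' @param object a `phantom_sample`.
#' @param ... unused.
#' @return A ggplot object faceting input, soft-tissue label and bone truth.
#' @exportS3Method ggplot2::autoplot
autoplot.phantom_sample <- function(object, ...) {
  layers <- list(input = object$input_image, soft = object$soft_label,
                 bone = object$bone_truth)
  df <- purrr::map_dfr(names(layers), function(nm) {
    m <- layers[[nm]]
    d <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
    d$value <- m[cbind(d$row, d$col)]
    d$layer <- nm
    d
  })
  df$layer <- factor(df$layer, levels = c("input", "soft", "bone"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::labs(
      title = sprintf("%s  (BMD %.2f g/cm^2)", object$sample_id,
                      object$bmd_true),
      x = NULL, y = NULL, fill = "gray"
    ) +
    ggplot2::theme_minimal()
}

training_curve_plot <- function(tidied, title) {
  ggplot2::ggplot(tidied, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                       colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = title, x = "epoch", y = "MSE",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Training-curve plots
#'
#' @param object a trained `unet_model` or `bmd_ann`.
#' @param ... unused.
#' @return A ggplot object of train/validation MSE per epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.unet_model <- function(object, ...) {
  training_curve_plot(tidy(object), "U-Net training")
}

#' @rdname autoplot.unet_model
#' @exportS3Method ggplot2::autoplot
autoplot.bmd_ann <- function(object, ...) {
  training_curve_plot(tidy(object), "BMD regressor training")
}

#' True-versus-predicted BMD scatter
#'
#' @param object a `bmd_pipeline_result`.
#' @param subset which subset to show (default `"validation"`).
#' @param ... unused.
#' @return A ggplot object, one facet per arm, with the identity line.
#' @exportS3Method ggplot2::autoplot
autoplot.bmd_pipeline_result <- function(object, subset = "validation", ...) {
  df <- object$predictions[object$predictions$subset == subset, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bmd_true, y = .data$bmd_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~arm) +
    ggplot2::coord_fixed(xlim = c(0.3, 1.4), ylim = c(0.3, 1.4)) +
    ggplot2::labs(x = "true BMD (g/cm^2)", y = "predicted BMD (g/cm^2)",
                  title = sprintf("BMD prediction (%s set)", subset)) +
    ggplot2::theme_minimal()
}
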