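## End-to-end orchestration: phantom cohort -> U-Net soft-tissue subtraction
## -> regional features -> ANN regressor -> paired evaluation.

#' Configuration of a full pipeline run
#'
#' One global seed deterministically derives the seeds of every stage, so a
#' run is reproducible bit-for-bit from its config.
#'
#' @param n cohort size (the reference protocol uses 300, split 240/60).
#' @param image_size raster side in pixels (divisible by `2^depth`).
#' @param noise_sd additive acquisition-noise sd of the phantoms.
#' @param unet_train_n number of training-split samples used to fit the
#'   U-Net (soft-tissue prediction is a per-pixel task, so a few dozen
#'   images supply ample supervision).
#' @param unet_epochs,unet_depth,unet_base U-Net training epochs and
#'   architecture.
#' @param unet_batch,unet_lr U-Net mini-batch size and SGD learning rate;
#'   with a few dozen training images, small batches buy plain SGD many
#'   more updates per epoch at identical cost.
#' @param ann_hidden,ann_max_epochs,ann_patience regressor architecture and
#'   early-stopping settings.
#' @param seed global integer seed.
#' @return An object of class `run_config`.
#' @examples
#' run_config(n = 40, image_size = 32, seed = 7)
#' @export
run_config <- function(n = 300L, image_size = 64L, noise_sd = 0.02,
                       unet_train_n = 48L, unet_epochs = 30L,
                       unet_depth = 3L, unet_base = 16L,
                       unet_batch = 2L, unet_lr = 0.08,
                       ann_hidden = c(32L, 16L, 8L), ann_max_epochs = 500L,
                       ann_patience = 20L, seed = 1L) {
  check_scalar(n, "n", lo = 1)
  check_scalar(seed, "seed")
  if (image_size %% 2^unet_depth != 0) {
    abort(sprintf("`image_size` must be divisible by 2^depth = %d.",
                  2^unet_depth))
  }
  phantom <- phantom_config(image_size = image_size, noise_sd = noise_sd,
                            seed = derive_seed(seed, 1))
  unet <- unet_spec(depth = unet_depth, base_channels = unet_base,
                    epochs = unet_epochs, batch_size = unet_batch,
                    learning_rate = unet_lr, seed = derive_seed(seed, 2))
  ann <- ann_spec(hidden = ann_hidden, max_epochs = ann_max_epochs,
                  patience = ann_patience, seed = derive_seed(seed, 3))
  structure(
    list(n = as.integer(n), phantom = phantom, unet = unet, ann = ann,
         unet_train_n = as.integer(min(unet_train_n, ceiling(0.8 * n))),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full BMD-prediction experiment
#'
#' Executes every stage on a synthetic cohort: generate phantoms, fit the
#' U-Net on a subset of the training split, subtract predicted soft tissue
#' from every radiograph, extract the 23-element features from both the
#' subtracted bone images (the `"subtracted"` arm) and the raw radiographs
#' (the `"raw"` arm), train one regressor per arm under identical seeds and
#' split, and evaluate both arms on both subsets.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-built [synthesize_cohort()] result (it must
#'   have been generated from `config$phantom`).
#' @return An object of class `bmd_pipeline_result`: a list with the cohort
#'   manifest, the split, the trained `unet` and per-arm `bmd_ann` models,
#'   the `predictions` tibble and the `reports` tibble.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) cohort <- synthesize_cohort(config$phantom, config$n)
  samples <- cohort$samples
  manifest <- cohort$manifest
  split <- split_dataset(manifest$sample_id, derive_seed(config$seed, 4))

  unet_ids <- split$train[seq_len(config$unet_train_n)]
  unet_pairs <- samples[match(unet_ids, manifest$sample_id)]
  unet <- train_unet(build_unet(config$unet), unet_pairs)

  by_id <- stats::setNames(samples, manifest$sample_id)
  bone_hat <- lapply(by_id, function(s) {
    subtract_soft_tissue(s$input_image, predict_soft_tissue(unet, s$input_image))
  })
  raw_imgs <- lapply(by_id, function(s) s$input_image)

  feats_sub <- extract_feature_table(manifest, images = bone_hat)
  feats_raw <- extract_feature_table(manifest, images = raw_imgs)

  fit_arm <- function(feats) {
    train_ann(feats, feats$bmd, config$ann, split)
  }
  ann_sub <- fit_arm(feats_sub)
  ann_raw <- fit_arm(feats_raw)

  predict_arm <- function(model, feats, arm) {
    pred <- predict_bmd(model, feats)
    tibble::tibble(
      arm = arm,
      sample_id = feats$sample_id,
      subset = ifelse(feats$sample_id %in% split$train, "train", "validation"),
      bmd_true = feats$bmd,
      bmd_pred = pred
    )
  }
  predictions <- dplyr::bind_rows(
    predict_arm(ann_sub, feats_sub, "subtracted"),
    predict_arm(ann_raw, feats_raw, "raw")
  )
  structure(
    list(config = config, manifest = manifest, split = split, unet = unet,
         ann = list(subtracted = ann_sub, raw = ann_raw),
         features = list(subtracted = feats_sub, raw = feats_raw),
         predictions = predictions,
         reports = evaluate_predictions(predictions)),
    class = "bmd_pipeline_result"
  )
}

#' @export
print.bmd_pipeline_result <- function(x, ...) {
  cat(sprintf("<bmd_pipeline_result> n = %d, %dx%d px\n",
              x$config$n, x$config$phantom$image_size,
              x$config$phantom$image_size))
  print(as.data.frame(x$reports))
  invisible(x)
}
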