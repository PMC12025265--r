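## Shared fixtures, computed lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

## Small phantom config used across module tests.
tiny_phantom <- function(seed = 11) {
  phantom_config(image_size = 32, seed = seed)
}

## A modest cohort for distributional properties (64 px to give the vertebra
## mask a realistic pixel count).
property_cohort <- function() {
  fixture("property_cohort", function() {
    synthesize_cohort(phantom_config(image_size = 64, seed = 2024), n = 200)
  })
}

## A small trained U-Net on an easy version of the soft-tissue task, reused
## by prediction-quality tests.
tiny_trained_unet <- function() {
  fixture("tiny_trained_unet", function() {
    cfg <- phantom_config(image_size = 32, seed = 7)
    pairs <- lapply(1:16, function(i) synthesize_sample(cfg, i))
    spec <- unet_spec(depth = 2, base_channels = 8, epochs = 40,
                      batch_size = 2, learning_rate = 0.08, seed = 3)
    list(
      cfg = cfg,
      pairs = pairs,
      fit = train_unet(build_unet(spec), pairs)
    )
  })
}

## Deterministic miniature feature table with a known linear signal, for
## regressor tests that need no imaging at all.
linear_feature_task <- function(n = 200, seed = 5) {
  with_seed(seed, {
    X <- matrix(rnorm(n * 23), n, 23,
                dimnames = list(NULL, bmdnet:::feature_names()))
    ## targets depend on two features only, mapped affinely into (0.3, 1.4)
    lin <- 0.85 + 0.108 * X[, 1] - 0.072 * X[, 2]
    y <- pmin(pmax(lin + rnorm(n, 0, 0.01), 0.32), 1.38)
    list(X = X, y = y)
  })
}
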