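test_that("built networks have the right shape, seed determinism and size", {
  spec <- unet_spec(depth = 2, base_channels = 4, seed = 5)
  m1 <- build_unet(spec)
  m2 <- build_unet(spec)
  expect_identical(m1$params, m2$params)
  x <- matrix(runif(64 * 64), 64, 64)
  y <- predict_soft_tissue(m1, x)
  expect_identical(dim(y), dim(x))
  expect_gte(min(y), 0)
  expect_lte(max(y), 1)
  expect_error(predict_soft_tissue(m1, matrix(0, 30, 30)), "divisible")
  ## parameter count against an independent enumeration of layer shapes:
  ## two 3x3 convs per encoder level, bottleneck, decoder with up-conv and
  ## two convs per level, 1x1 head
  count_conv3 <- function(cin, cout) 9 * cin * cout + cout
  expected <- count_conv3(1, 4) + count_conv3(4, 4) +      # enc1
    count_conv3(4, 8) + count_conv3(8, 8) +                # enc2
    count_conv3(8, 16) + count_conv3(16, 16) +             # bottleneck
    count_conv3(16, 8) + count_conv3(16, 8) + count_conv3(8, 8) +  # dec2
    count_conv3(8, 4) + count_conv3(8, 4) + count_conv3(4, 4) +    # dec1
    (4 * 1 + 1)                                            # 1x1 head
  expect_identical(n_parameters(m1), expected)
})

test_that("mse_loss equals the scalar-loop oracle", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(0, 0), c(1, 1)), 1.0)
  set.seed(31)
  y <- matrix(runif(40), 5, 8)
  yh <- matrix(runif(40), 5, 8)
  acc <- 0
  for (i in seq_along(y)) acc <- acc + (y[i] - yh[i])^2
  expect_equal(mse_loss(y, yh), acc / length(y))
  expect_error(mse_loss(1:3, 1:4), "shape")
})

test_that("sgd_step matches plain gradient descent and its closed form", {
  expect_equal(sgd_step(1.0, 0.5, 0.1), 0.95)
  expect_equal(sgd_step(3.2, 0, 0.1), 3.2)
  ## J(theta) = theta^2, eta = 0.1: theta_t = 0.8^t
  th <- 1
  for (t in 1:50) th <- sgd_step(th, 2 * th, 0.1)
  expect_equal(th, 0.8^50)
  expect_lt(abs(th), 1e-4)
  expect_error(sgd_step(1, NaN, 0.1), "non-finite")
  ## nested parameter lists update every leaf
  p <- list(a = list(W = matrix(1, 2, 2), b = c(1, 1)))
  g <- list(a = list(W = matrix(0.5, 2, 2), b = c(0.5, 0.5)))
  p2 <- sgd_step(p, g, 1)
  expect_equal(p2$a$W, matrix(0.5, 2, 2))
})

test_that("backpropagation matches numerical gradients", {
  spec <- unet_spec(depth = 2, base_channels = 2, seed = 42)
  m <- build_unet(spec)
  set.seed(7)
  x <- matrix(runif(16 * 16), 16, 16)
  y <- matrix(runif(16 * 16), 16, 16)
  loss_at <- function(params) {
    out <- bmdnet:::unet_forward(params, spec, x)$y
    mean((as.vector(out) - as.vector(y))^2)
  }
  fw <- bmdnet:::unet_forward(m$params, spec, x, keep = TRUE)
  dy <- 2 * (fw$y - array(y, dim(fw$y))) / length(fw$y)
  g <- bmdnet:::unet_backward(m$params, spec, fw$cache, dy)
  eps <- 1e-6
  for (nm in c("enc1_c1", "bott_c2", "dec1_up", "out")) {
    p <- m$params
    i <- 1L
    p[[nm]]$W[i] <- p[[nm]]$W[i] + eps
    up <- loss_at(p)
    p[[nm]]$W[i] <- p[[nm]]$W[i] - 2 * eps
    dn <- loss_at(p)
    expect_equal(g[[nm]]$W[i], (up - dn) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("training reduces the loss, is seeded, and beats a mean baseline", {
  tu <- tiny_trained_unet()
  h <- tu$fit$history
  expect_true(all(is.finite(h$train_mse)) && all(h$train_mse >= 0))
  expect_lt(h$train_mse[nrow(h)], 0.5 * h$train_mse[1])
  ## median loss over last 5 epochs below median over first 5
  expect_lt(median(tail(h$train_mse, 5)), median(head(h$train_mse, 5)))
  ## bit-identical retraining under the same seed
  spec <- unet_spec(depth = 2, base_channels = 8, epochs = 3,
                    batch_size = 2, learning_rate = 0.08, seed = 3)
  f1 <- train_unet(build_unet(spec), tu$pairs[1:6])
  f2 <- train_unet(build_unet(spec), tu$pairs[1:6])
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  ## held-out prediction better on average than the training-mean image
  mean_img <- Reduce(`+`, lapply(tu$pairs, `[[`, "soft_label")) /
    length(tu$pairs)
  mse_net <- mse_base <- numeric(0)
  for (i in 501:510) {
    s <- synthesize_sample(tu$cfg, i)
    mse_net <- c(mse_net,
                 mse_loss(s$soft_label,
                          predict_soft_tissue(tu$fit, s$input_image)))
    mse_base <- c(mse_base, mse_loss(s$soft_label, mean_img))
  }
  expect_lt(mean(mse_net), mean(mse_base))
})

test_that("a no-bone task drives validation loss to the noise floor", {
  cfg <- phantom_config(image_size = 32, noise_sd = 0.02, seed = 21)
  pairs <- lapply(1:10, function(i) {
    s <- synthesize_sample(cfg, i)
    list(input_image = s$input_image, soft_label = s$input_image)
  })
  spec <- unet_spec(depth = 2, base_channels = 8, epochs = 12,
                    batch_size = 4, seed = 9)
  fit <- train_unet(build_unet(spec), pairs)
  ## identity task: the model can reach (near) zero error
  expect_lt(tail(fit$history$val_mse, 1), 5e-3)
})

test_that("subtraction recovers the bone image up to clamping and noise", {
  expect_equal(subtract_soft_tissue(matrix(0.5, 2, 2), matrix(0.5, 2, 2)),
               matrix(0, 2, 2))
  m <- matrix(runif(16), 4, 4)
  expect_equal(subtract_soft_tissue(m, matrix(0, 4, 4)), m)
  expect_equal(subtract_soft_tissue(matrix(0.7, 2, 2), matrix(0.9, 2, 2)),
               matrix(0, 2, 2))
  expect_error(subtract_soft_tissue(m, matrix(0, 2, 2)), "shape")
  ## reconstruction bound with the true soft label
  cfg <- phantom_config(image_size = 64, noise_sd = 0.02, seed = 13)
  s <- synthesize_sample(cfg, 1)
  recon <- subtract_soft_tissue(s$input_image, s$soft_label)
  expect_lt(mse_loss(s$bone_truth, recon), 2 * cfg$noise_sd^2)
})

test_that("checkpoints restore a model exactly", {
  tu <- tiny_trained_unet()
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(tu$fit, p)
  back <- load_checkpoint(p)
  expect_identical(back$params, tu$fit$params)
  x <- tu$pairs[[1]]$input_image
  expect_identical(predict_soft_tissue(back, x),
                   predict_soft_tissue(tu$fit, x))
})
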