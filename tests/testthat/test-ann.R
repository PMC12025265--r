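test_that("activations match their definitions and bounds", {
  expect_equal(relu(-3), 0)
  expect_equal(relu(0), 0)
  expect_equal(relu(2.5), 2.5)
  expect_equal(output_activation(0), 0.85)
  ## asymptotes of 0.55 * tanh(x) + 0.85: range (0.3, 1.4), span 1.1
  expect_equal(round(output_activation(50), 1), 1.4)
  expect_equal(round(output_activation(-50), 1), 0.3)
  expect_equal(0.55 * 1 + 0.85 - (0.55 * -1 + 0.85), 1.1)
  x <- seq(-6, 6, length.out = 200)
  fx <- output_activation(x)
  expect_true(all(diff(fx) > 0))           # strictly increasing
  expect_true(all(fx > 0.3 & fx < 1.4))    # open range
})

test_that("the 1:4 split is seeded, disjoint and rounds ties to training", {
  s <- split_dataset(1:300, seed = 1)
  expect_length(s$train, 240)
  expect_length(s$validation, 60)
  expect_length(intersect(s$train, s$validation), 0)
  expect_setequal(c(s$train, s$validation), 1:300)
  expect_identical(split_dataset(1:300, seed = 1), s)
  expect_false(identical(split_dataset(1:300, seed = 2)$train, s$train))
  odd <- split_dataset(1:7, seed = 3)
  expect_length(odd$train, 6)   # ceiling(0.8 * 7)
  expect_error(split_dataset(1:4, seed = 1), "at least 5")
})

test_that("an untrained miniature network matches a hand-traced forward pass", {
  ## 2-2-2-2-1 stack with fixed weights, traced with scalar arithmetic
  params <- list(
    L1 = list(W = matrix(c(0.5, -0.25, 0.1, 0.3), 2, 2), b = c(0.1, -0.2)),
    L2 = list(W = matrix(c(0.2, 0.4, -0.3, 0.6), 2, 2), b = c(0, 0.05)),
    L3 = list(W = matrix(c(1, -1, 0.5, 0.5), 2, 2), b = c(0.1, 0.1)),
    L4 = list(W = matrix(c(0.7, -0.2), 2, 1), b = 0.05)
  )
  x <- c(0.3, -0.4)
  h <- x
  for (l in 1:3) {
    h <- pmax(as.vector(h %*% params[[l]]$W) + params[[l]]$b, 0)
  }
  z <- sum(h * params$L4$W) + params$L4$b
  oracle <- 0.55 * tanh(z) + 0.85
  got <- bmdnet:::ann_forward(params, matrix(x, 1, 2))$yhat
  expect_equal(got, oracle)
  ## and the zero vector reduces to the bias path
  z0 <- {
    h <- rep(0, 2)
    for (l in 1:3) h <- pmax(as.vector(h %*% params[[l]]$W) + params[[l]]$b, 0)
    sum(h * params$L4$W) + params$L4$b
  }
  expect_equal(bmdnet:::ann_forward(params, matrix(0, 1, 2))$yhat,
               0.55 * tanh(z0) + 0.85)
})

test_that("regressor training solves a linear task and stops early", {
  task <- linear_feature_task(n = 200)
  split <- split_dataset(1:200, seed = 2)
  spec <- ann_spec(learning_rate = 0.05, batch_size = 8, max_epochs = 800,
                   seed = 4)
  fit <- train_ann(task$X, task$y, spec, split)
  expect_lt(min(fit$history$val_mse), 0.01)
  expect_lte(nrow(fit$history), spec$max_epochs)
  ## best-validation property of early stopping
  expect_lte(fit$history$val_mse[fit$best_epoch],
             min(fit$history$val_mse) + spec$tol)
  ## reproducibility
  fit2 <- train_ann(task$X, task$y, spec, split)
  expect_identical(fit$history, fit2$history)
  ## constant targets: patience halts before the epoch ceiling
  y_const <- rep(0.85, 200)
  spec_fast <- ann_spec(patience = 10, max_epochs = 400, seed = 4)
  fit_const <- train_ann(task$X, y_const, spec_fast, split)
  expect_lt(nrow(fit_const$history), spec_fast$max_epochs)
  ## out-of-range targets are unreachable by the bounded activation
  expect_error(train_ann(task$X, rep(1.5, 200), spec, split),
               "activation range")
})

test_that("predictions are pure, dimension-checked and range-safe", {
  task <- linear_feature_task(n = 60)
  split <- split_dataset(1:60, seed = 7)
  fit <- train_ann(task$X, task$y, ann_spec(max_epochs = 50, seed = 1), split)
  p1 <- predict_bmd(fit, task$X[3, ])
  p2 <- predict_bmd(fit, task$X[c(3, 3), ])
  expect_equal(p2, rep(p1, 2))
  expect_error(predict_bmd(fit, rnorm(10)), "23")
  ## range safety holds for arbitrary inputs and for an untrained model
  wild <- matrix(rnorm(50 * 23, 0, 100), 50, 23)
  expect_true(all(predict_bmd(fit, wild) > 0.3 &
                    predict_bmd(fit, wild) < 1.4))
})
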