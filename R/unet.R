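## U-Net soft-tissue predictor: architecture, seeded initialization,
## forward/backward passes, plain-SGD training loop, prediction and the
## bone-image recovery by subtraction.

#' U-Net architecture and training specification
#'
#' @param depth number of encoder levels (each: two 3x3 convolutions + ReLU,
#'   then 2x2 max pooling). The input side must be divisible by `2^depth`.
#' @param base_channels feature channels at the first encoder level; widths
#'   double per level down to the bottleneck.
#' @param learning_rate plain SGD step size of the update `theta - eta * g`.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param val_fraction fraction of pairs held out for validation.
#' @param seed integer seed controlling initialization, the train/validation
#'   assignment and the per-epoch shuffle.
#' @return An object of class `unet_spec`.
#' @examples
#' unet_spec(depth = 2, base_channels = 8)
#' @export
unet_spec <- function(depth = 3L, base_channels = 16L, learning_rate = 0.05,
                      epochs = 20L, batch_size = 8L, val_fraction = 0.2,
                      seed = 1L) {
  check_scalar(depth, "depth", lo = 1)
  check_scalar(base_channels, "base_channels", lo = 1)
  check_scalar(learning_rate, "learning_rate", lo = 0, strict = TRUE)
  check_scalar(epochs, "epochs", lo = 1)
  check_scalar(batch_size, "batch_size", lo = 1)
  check_scalar(val_fraction, "val_fraction", lo = 0, hi = 0.9)
  check_scalar(seed, "seed")
  structure(
    list(depth = as.integer(depth), base_channels = as.integer(base_channels),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), val_fraction = val_fraction,
         seed = as.integer(seed)),
    class = "unet_spec"
  )
}

## Enumerate every convolution in the network with its channel counts.
unet_layer_table <- function(depth, base) {
  ch <- function(k) base * 2^(k - 1)
  rows <- list()
  for (k in seq_len(depth)) {
    cin <- if (k == 1) 1L else ch(k - 1)
    rows[[length(rows) + 1]] <- list(sprintf("enc%d_c1", k), "conv3", cin, ch(k))
    rows[[length(rows) + 1]] <- list(sprintf("enc%d_c2", k), "conv3", ch(k), ch(k))
  }
  bc <- base * 2^depth
  rows[[length(rows) + 1]] <- list("bott_c1", "conv3", ch(depth), bc)
  rows[[length(rows) + 1]] <- list("bott_c2", "conv3", bc, bc)
  for (k in rev(seq_len(depth))) {
    rows[[length(rows) + 1]] <- list(sprintf("dec%d_up", k), "conv3",
                                     base * 2^k, ch(k))
    rows[[length(rows) + 1]] <- list(sprintf("dec%d_c1", k), "conv3",
                                     base * 2^k, ch(k))
    rows[[length(rows) + 1]] <- list(sprintf("dec%d_c2", k), "conv3",
                                     ch(k), ch(k))
  }
  rows[[length(rows) + 1]] <- list("out", "conv1", base, 1L)
  tibble::tibble(
    name = vapply(rows, `[[`, "", 1),
    type = vapply(rows, `[[`, "", 2),
    cin = vapply(rows, function(r) as.integer(r[[3]]), 1L),
    cout = vapply(rows, function(r) as.integer(r[[4]]), 1L)
  )
}

#' Build a U-Net model
#'
#' Constructs the encoder-decoder network: `depth` encoder blocks of two 3x3
#' convolutions with ReLU followed by 2x2 max pooling, a two-convolution
#' bottleneck, a mirrored decoder using nearest-neighbour upsampling + 3x3
#' convolution and channel-concatenating skip connections from the encoder,
#' and a 1x1 single-channel output head. Weights use seeded He
#' initialization, so two builds from the same spec are identical.
#'
#' @param spec a [unet_spec()].
#' @return An object of class `unet_model` with elements `spec`, `params`
#'   (named list of weight matrices and biases) and `layers`.
#' @examples
#' m <- build_unet(unet_spec(depth = 2, base_channels = 4))
#' n_parameters(m)
#' @export
build_unet <- function(spec) {
  stopifnot(inherits(spec, "unet_spec"))
  layers <- unet_layer_table(spec$depth, spec$base_channels)
  params <- with_seed(derive_seed(spec$seed, 101), {
    out <- list()
    for (i in seq_len(nrow(layers))) {
      cin <- layers$cin[i]; cout <- layers$cout[i]
      fan <- if (layers$type[i] == "conv3") 9L * cin else cin
      ## the 1x1 head starts at zero so, with the global residual
      ## connection, the initial network is exactly the identity
      W <- if (layers$name[i] == "out") {
        matrix(0, fan, cout)
      } else {
        matrix(rnorm(fan * cout, 0, sqrt(2 / fan)), fan, cout)
      }
      out[[layers$name[i]]] <- list(W = W, b = numeric(cout))
    }
    out
  })
  structure(list(spec = spec, params = params, layers = layers,
                 history = NULL),
            class = "unet_model")
}

#' Count model parameters
#'
#' @param model a `unet_model` or `bmd_ann` object.
#' @return Total number of trainable scalars.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params,
             function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth %d, base %d channels, %d parameters%s\n",
              x$spec$depth, x$spec$base_channels, n_parameters(x),
              if (is.null(x$history)) " (untrained)" else
                sprintf(", trained %d epochs", nrow(x$history))))
  invisible(x)
}

check_unet_input <- function(model, image) {
  check_raster(image, "image")
  side <- 2^model$spec$depth
  if (nrow(image) %% side != 0 || ncol(image) %% side != 0) {
    abort(sprintf("image sides must be divisible by 2^depth = %d.", side))
  }
}

## Full forward pass. Returns the linear output map and, if keep = TRUE, the
## caches required by unet_backward.
unet_forward <- function(params, spec, x, keep = FALSE) {
  depth <- spec$depth
  h <- x
  if (is.matrix(h)) dim(h) <- c(dim(x), 1L)
  x0 <- h
  cache <- if (keep) list(enc = vector("list", depth),
                          dec = vector("list", depth)) else NULL
  skips <- vector("list", depth)
  for (k in seq_len(depth)) {
    cdim1 <- dim(h)
    f1 <- conv3_forward(h, params[[sprintf("enc%d_c1", k)]]$W,
                        params[[sprintf("enc%d_c1", k)]]$b)
    a1 <- relu_forward(f1$y)
    cdim2 <- dim(a1)
    f2 <- conv3_forward(a1, params[[sprintf("enc%d_c2", k)]]$W,
                        params[[sprintf("enc%d_c2", k)]]$b)
    a2 <- relu_forward(f2$y)
    skips[[k]] <- a2
    pf <- pool_forward(a2)
    if (keep) {
      cache$enc[[k]] <- list(xdim1 = cdim1, cols1 = f1$cols, pre1 = f1$y,
                             xdim2 = cdim2, cols2 = f2$cols, pre2 = f2$y,
                             pf = pf)
    }
    h <- pf$y
  }
  bdim1 <- dim(h)
  fb1 <- conv3_forward(h, params$bott_c1$W, params$bott_c1$b)
  ab1 <- relu_forward(fb1$y)
  bdim2 <- dim(ab1)
  fb2 <- conv3_forward(ab1, params$bott_c2$W, params$bott_c2$b)
  h <- relu_forward(fb2$y)
  if (keep) {
    cache$bott <- list(xdim1 = bdim1, cols1 = fb1$cols, pre1 = fb1$y,
                       xdim2 = bdim2, cols2 = fb2$cols, pre2 = fb2$y)
  }
  for (k in rev(seq_len(depth))) {
    up <- upsample_forward(h)
    udim <- dim(up)
    fu <- conv3_forward(up, params[[sprintf("dec%d_up", k)]]$W,
                        params[[sprintf("dec%d_up", k)]]$b)
    au <- relu_forward(fu$y)
    cat_in <- concat_channels(au, skips[[k]])
    ddim1 <- dim(cat_in)
    f1 <- conv3_forward(cat_in, params[[sprintf("dec%d_c1", k)]]$W,
                        params[[sprintf("dec%d_c1", k)]]$b)
    a1 <- relu_forward(f1$y)
    ddim2 <- dim(a1)
    f2 <- conv3_forward(a1, params[[sprintf("dec%d_c2", k)]]$W,
                        params[[sprintf("dec%d_c2", k)]]$b)
    h <- relu_forward(f2$y)
    if (keep) {
      cache$dec[[k]] <- list(udim = udim, colsu = fu$cols, preu = fu$y,
                             n_up = dim(au)[3],
                             xdim1 = ddim1, cols1 = f1$cols, pre1 = f1$y,
                             xdim2 = ddim2, cols2 = f2$cols, pre2 = f2$y)
    }
  }
  fo <- conv1_forward(h, params$out$W, params$out$b)
  ## global residual connection: the head predicts the correction to the
  ## input, so the identity (soft = input) is the network's starting point
  y <- fo$y + x0
  if (keep) {
    cache$out <- list(X = fo$X, xdim = dim(h))
    cache$y <- y
  }
  list(y = y, cache = cache)
}

## Backward pass; returns gradients in the same named structure as params.
unet_backward <- function(params, spec, cache, dy) {
  depth <- spec$depth
  grads <- list()
  bo <- conv1_backward(dy, cache$out$X, params$out$W, cache$out$xdim)
  grads$out <- list(W = bo$dW, b = bo$db)
  dh <- bo$dx
  for (k in seq_len(depth)) {           # decoder levels back, 1 .. depth
    cc <- cache$dec[[k]]
    dh <- relu_backward(dh, cc$pre2)
    b2 <- conv3_backward(dh, cc$cols2, params[[sprintf("dec%d_c2", k)]]$W,
                         cc$xdim2)
    grads[[sprintf("dec%d_c2", k)]] <- list(W = b2$dW, b = b2$db)
    d1 <- relu_backward(b2$dx, cc$pre1)
    b1 <- conv3_backward(d1, cc$cols1, params[[sprintf("dec%d_c1", k)]]$W,
                         cc$xdim1)
    grads[[sprintf("dec%d_c1", k)]] <- list(W = b1$dW, b = b1$db)
    n_up <- cc$n_up
    d_cat <- b1$dx
    d_au <- d_cat[, , seq_len(n_up), drop = FALSE]
    d_skip <- d_cat[, , n_up + seq_len(dim(d_cat)[3] - n_up), drop = FALSE]
    du <- relu_backward(d_au, cc$preu)
    bu <- conv3_backward(du, cc$colsu, params[[sprintf("dec%d_up", k)]]$W,
                         cc$udim)
    grads[[sprintf("dec%d_up", k)]] <- list(W = bu$dW, b = bu$db)
    ## gradient flowing further down the decoder chain (to level k+1 input)
    dh_next <- upsample_backward(bu$dx)
    ## stash the skip gradient; it joins the encoder backward pass later
    cache$enc[[k]]$d_skip <- d_skip
    dh <- dh_next
  }
  ## dh now reaches the bottleneck output
  db2pre <- relu_backward(dh, cache$bott$pre2)
  bb2 <- conv3_backward(db2pre, cache$bott$cols2, params$bott_c2$W,
                        cache$bott$xdim2)
  grads$bott_c2 <- list(W = bb2$dW, b = bb2$db)
  db1pre <- relu_backward(bb2$dx, cache$bott$pre1)
  bb1 <- conv3_backward(db1pre, cache$bott$cols1, params$bott_c1$W,
                        cache$bott$xdim1)
  grads$bott_c1 <- list(W = bb1$dW, b = bb1$db)
  dh <- bb1$dx
  for (k in rev(seq_len(depth))) {      # encoder levels back, depth .. 1
    cc <- cache$enc[[k]]
    d_a2 <- pool_backward(dh, cc$pf) + cc$d_skip
    d2 <- relu_backward(d_a2, cc$pre2)
    b2 <- conv3_backward(d2, cc$cols2, params[[sprintf("enc%d_c2", k)]]$W,
                         cc$xdim2)
    grads[[sprintf("enc%d_c2", k)]] <- list(W = b2$dW, b = b2$db)
    d1 <- relu_backward(b2$dx, cc$pre1)
    b1 <- conv3_backward(d1, cc$cols1, params[[sprintf("enc%d_c1", k)]]$W,
                         cc$xdim1)
    grads[[sprintf("enc%d_c1", k)]] <- list(W = b1$dW, b = b1$db)
    dh <- b1$dx
  }
  grads
}

#' Mean squared error
#'
#' The training loss: the mean of squared element-wise differences between
#' target and prediction.
#'
#' @param y,yhat numeric vectors, matrices or arrays of identical shape, or
#'   lists of such rasters (a batch).
#' @return A single non-negative number.
#' @examples
#' mse_loss(c(0, 0), c(1, 1))
#' @export
mse_loss <- function(y, yhat) {
  if (is.list(y) || is.list(yhat)) {
    if (!is.list(y) || !is.list(yhat) || length(y) != length(yhat)) {
      abort("batch lists must have equal length.")
    }
    y <- unlist(y, use.names = FALSE)
    yhat <- unlist(yhat, use.names = FALSE)
  }
  if (length(y) != length(yhat) ||
      !identical(dim(y) %||% length(y), dim(yhat) %||% length(yhat))) {
    abort("`y` and `yhat` must have identical shape.")
  }
  if (length(y) < 1L) abort("need at least one element.")
  mean((as.numeric(y) - as.numeric(yhat))^2)
}

#' One plain stochastic-gradient-descent step
#'
#' Updates every parameter as `theta - eta * g` — no momentum, no weight
#' decay. Accepts either bare numeric parameters or the nested named lists
#' used by the package's models.
#'
#' @param theta parameters (numeric, or a nested list of numerics).
#' @param gradient gradient with the same structure as `theta`.
#' @param eta learning rate (> 0).
#' @return Updated parameters with the structure of `theta`.
#' @examples
#' sgd_step(1.0, 0.5, 0.1)
#' @export
sgd_step <- function(theta, gradient, eta) {
  check_scalar(eta, "eta", lo = 0, strict = TRUE)
  step <- function(p, g) {
    if (is.list(p)) {
      for (nm in names(p)) p[[nm]] <- step(p[[nm]], g[[nm]])
      p
    } else {
      if (any(!is.finite(g))) {
        abort("training error: non-finite gradient encountered.")
      }
      p - eta * g
    }
  }
  step(theta, gradient)
}

## Zero-filled gradient accumulator matching `params`.
zero_like <- function(params) {
  lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
}

add_grads <- function(acc, g, scale = 1) {
  for (nm in names(g)) {
    acc[[nm]]$W <- acc[[nm]]$W + scale * g[[nm]]$W
    acc[[nm]]$b <- acc[[nm]]$b + scale * g[[nm]]$b
  }
  acc
}

#' Train the U-Net soft-tissue predictor
#'
#' Minimizes the mean squared error between the predicted and true
#' soft-tissue images over seeded, shuffled mini-batches with plain SGD.
#' The train/validation assignment is fixed by the spec seed before the
#' first epoch. Training is bit-reproducible for a given `(model, pairs)`.
#'
#' @param model an untrained (or previously trained) [build_unet()] model.
#' @param pairs a list of `phantom_sample` objects, or of lists with elements
#'   `input_image` and `soft_label`.
#' @param spec optional [unet_spec()] overriding `model$spec` training
#'   fields (epochs, batch size, learning rate, seed).
#' @return The trained `unet_model`, with `$history` a tibble of
#'   `(epoch, train_mse, val_mse)`.
#' @export
train_unet <- function(model, pairs, spec = model$spec) {
  stopifnot(inherits(model, "unet_model"))
  if (!is.list(pairs) || length(pairs) < 2L) {
    abort("`pairs` must hold at least two training samples.")
  }
  xs <- lapply(pairs, function(p) p$input_image)
  ys <- lapply(pairs, function(p) p$soft_label)
  for (x in xs) check_unet_input(model, x)
  n <- length(xs)
  params <- model$params
  n_val <- max(1L, floor(spec$val_fraction * n))
  ord <- with_seed(derive_seed(spec$seed, 202), sample.int(n))
  val_idx <- ord[seq_len(n_val)]
  tr_idx <- setdiff(ord, val_idx)
  eval_set <- function(idx) {
    mean(vapply(idx, function(i) {
      yhat <- unet_forward(params, spec, xs[[i]])$y
      dim(yhat) <- dim(ys[[i]])
      mse_loss(ys[[i]], yhat)
    }, numeric(1)))
  }
  history <- vector("list", spec$epochs)
  batch_plan <- with_seed(derive_seed(spec$seed, 303), {
    lapply(seq_len(spec$epochs), function(e) sample(tr_idx))
  })
  for (epoch in seq_len(spec$epochs)) {
    sh <- batch_plan[[epoch]]
    batch_losses <- c()
    i <- 1L
    while (i <= length(sh)) {
      idx <- sh[i:min(i + spec$batch_size - 1L, length(sh))]
      acc <- zero_like(params)
      bl <- 0
      for (j in idx) {
        fw <- unet_forward(params, spec, xs[[j]], keep = TRUE)
        yhat <- fw$y
        target <- ys[[j]]
        dim(target) <- dim(yhat)
        bl <- bl + mean((yhat - target)^2)
        ## the loss acts on the linear output; the [0,1] clamp is applied
        ## only at prediction time so gradients never die at the bounds
        dy <- 2 * (yhat - target) / length(yhat)
        g <- unet_backward(params, spec, fw$cache, dy)
        acc <- add_grads(acc, g, scale = 1 / length(idx))
      }
      bl <- bl / length(idx)
      if (!is.finite(bl)) abort("training error: non-finite loss.")
      params <- sgd_step(params, acc, spec$learning_rate)
      batch_losses <- c(batch_losses, bl)
      i <- i + spec$batch_size
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch,
      train_mse = mean(batch_losses),
      val_mse = eval_set(val_idx)
    )
  }
  model$params <- params
  model$spec <- spec
  model$history <- dplyr::bind_rows(history)
  model
}

#' Predict the soft-tissue image
#'
#' @param model a trained `unet_model`.
#' @param image a square grayscale matrix with sides divisible by
#'   `2^depth`.
#' @return A matrix of the same shape, clamped to `[0, 1]`.
#' @export
predict_soft_tissue <- function(model, image) {
  stopifnot(inherits(model, "unet_model"))
  check_unet_input(model, image)
  y <- unet_forward(model$params, model$spec, image)$y
  dim(y) <- dim(image)
  clamp(y)
}

#' Recover the bone-dominant image by subtraction
#'
#' Subtracts the predicted soft-tissue image from the original radiograph and
#' clamps at zero, leaving the bone-dominant residual.
#'
#' @param original,soft numeric matrices of identical shape.
#' @return `clamp(original - soft, 0, 1)`.
#' @examples
#' subtract_soft_tissue(matrix(0.7, 2, 2), matrix(0.9, 2, 2))
#' @export
subtract_soft_tissue <- function(original, soft) {
  check_raster(original, "original")
  check_raster(soft, "soft")
  if (!same_shape(original, soft)) abort("shapes must match.")
  clamp(original - soft)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive of the named parameter tensors with
#' the spec (and, for the regressor, the training-set standardization
#' statistics) embedded as metadata.
#'
#' @param model a `unet_model` or `bmd_ann`.
#' @param path checkpoint file path.
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: the
#'   restored model object.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
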