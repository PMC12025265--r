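## The BMD regressor: a small feed-forward network with ReLU hidden layers
## and a bounded tanh output activation, trained with plain mini-batch SGD
## and early stopping on validation loss.

#' Rectified linear unit
#'
#' @param x numeric vector.
#' @return `max(0, x)`, element-wise.
#' @examples
#' relu(c(-3, 0, 2.5))
#' @export
relu <- function(x) pmax(x, 0)

#' Bounded output activation of the BMD regressor
#'
#' `f(x) = 0.55 * tanh(x) + 0.85`: strictly increasing, with open range
#' (0.3, 1.4) g/cm^2 — the biologically plausible lumbar BMD band. The
#' amplitude 0.55 compresses the output span to 1.1 units; the offset 0.85
#' centres it on the band.
#'
#' @param x numeric vector (pre-activation).
#' @return Values in (0.3, 1.4).
#' @examples
#' output_activation(0)      # 0.85
#' output_activation(50)     # ~ 1.4
#' @export
output_activation <- function(x) 0.55 * tanh(x) + 0.85

#' Split sample ids into training and validation sets
#'
#' Seeded shuffle, then the first 80% of ids become the training set and the
#' remainder the validation set (a 1:4 validation:training ratio; rounding
#' ties go to training).
#'
#' @param ids vector of sample ids (>= 5).
#' @param seed integer seed.
#' @return An object of class `split_index`: a list with `train` and
#'   `validation` id vectors.
#' @examples
#' s <- split_dataset(1:300, seed = 1)
#' lengths(s)
#' @export
split_dataset <- function(ids, seed) {
  if (length(ids) < 5L) abort("need at least 5 ids to split 80/20.")
  if (anyDuplicated(ids)) abort("`ids` must be unique.")
  ord <- with_seed(seed, sample(ids))
  n_train <- ceiling(0.8 * length(ids))
  structure(
    list(train = ord[seq_len(n_train)],
         validation = ord[(n_train + 1L):length(ord)]),
    class = "split_index"
  )
}

#' @export
print.split_index <- function(x, ...) {
  cat(sprintf("<split_index> %d training / %d validation (1:4)\n",
              length(x$train), length(x$validation)))
  invisible(x)
}

#' ANN regressor specification
#'
#' @param hidden integer vector of exactly three hidden-layer widths.
#' @param learning_rate plain SGD step size.
#' @param max_epochs training-epoch ceiling.
#' @param patience epochs without validation improvement before halting.
#' @param tol minimum validation-loss improvement that resets patience.
#' @param batch_size mini-batch size.
#' @param seed integer seed for initialization and shuffling.
#' @return An object of class `ann_spec` (`input_dim` fixed at 23; output
#'   activation constants a = 0.55, b = 0.85).
#' @examples
#' ann_spec()
#' @export
ann_spec <- function(hidden = c(32L, 16L, 8L), learning_rate = 0.005,
                     max_epochs = 500L, patience = 20L, tol = 1e-5,
                     batch_size = 16L, seed = 1L) {
  if (length(hidden) != 3L || any(hidden < 1)) {
    abort("`hidden` must give exactly three positive widths.")
  }
  check_scalar(learning_rate, "learning_rate", lo = 0, strict = TRUE)
  check_scalar(max_epochs, "max_epochs", lo = 1)
  check_scalar(patience, "patience", lo = 1)
  check_scalar(tol, "tol", lo = 0)
  check_scalar(batch_size, "batch_size", lo = 1)
  check_scalar(seed, "seed")
  structure(
    list(input_dim = 23L, hidden = as.integer(hidden), a = 0.55, b = 0.85,
         learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), tol = tol,
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "ann_spec"
  )
}

## Seeded He/Xavier-style initialization of the 23-h1-h2-h3-1 stack.
ann_init <- function(spec) {
  sizes <- c(spec$input_dim, spec$hidden, 1L)
  with_seed(derive_seed(spec$seed, 11), {
    params <- list()
    n_lay <- length(sizes) - 1L
    for (l in seq_len(n_lay)) {
      fan <- sizes[l]
      ## hidden layers: He init. Output layer: zeros, so the initial
      ## pre-activation is 0 and every prediction starts at the band
      ## midpoint 0.85 with the tanh unsaturated — a saturated start pins
      ## predictions at the bounds where the gradient vanishes.
      W <- if (l == n_lay) {
        matrix(0, fan, sizes[l + 1L])
      } else {
        matrix(rnorm(fan * sizes[l + 1L], 0, sqrt(2 / fan)),
               fan, sizes[l + 1L])
      }
      params[[paste0("L", l)]] <- list(W = W, b = numeric(sizes[l + 1L]))
    }
    params
  })
}

## Forward pass on a standardized feature matrix (n x 23). Returns the
## prediction vector and per-layer caches for backprop.
ann_forward <- function(params, X, a = 0.55, b = 0.85) {
  h <- X
  caches <- list()
  n_layers <- length(params)
  for (l in seq_len(n_layers - 1L)) {
    z <- h %*% params[[l]]$W + rep(params[[l]]$b, each = nrow(h))
    caches[[l]] <- list(input = h, z = z)
    h <- relu(z)
  }
  zo <- h %*% params[[n_layers]]$W + rep(params[[n_layers]]$b, each = nrow(h))
  caches[[n_layers]] <- list(input = h, z = zo)
  list(yhat = as.vector(a * tanh(zo) + b), caches = caches)
}

ann_backward <- function(params, caches, yhat, y, a = 0.55) {
  n <- length(y)
  n_layers <- length(params)
  zo <- caches[[n_layers]]$z
  dz <- (2 * (yhat - y) / n) * a * (1 - tanh(zo)^2)
  dim(dz) <- c(n, 1L)
  grads <- vector("list", n_layers)
  names(grads) <- names(params)
  for (l in rev(seq_len(n_layers))) {
    inp <- caches[[l]]$input
    grads[[l]] <- list(W = crossprod(inp, dz), b = colSums(dz))
    if (l > 1L) {
      dh <- tcrossprod(dz, params[[l]]$W)
      dz <- dh * (caches[[l - 1L]]$z > 0)
    }
  }
  grads
}

## Coerce a feature table/matrix to the n x 23 numeric matrix in canonical
## column order.
as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    cols <- feature_names()
    missing <- setdiff(cols, names(features))
    if (length(missing)) {
      abort(sprintf("feature table lacks columns: %s",
                    paste(missing, collapse = ", ")))
    }
    features <- as.matrix(features[, cols])
  }
  if (is.numeric(features) && is.null(dim(features))) {
    features <- matrix(features, nrow = 1L)
  }
  if (ncol(features) != 23L) {
    abort(sprintf("feature input must have 23 columns, got %d.",
                  ncol(features)))
  }
  storage.mode(features) <- "double"
  features
}

#' Train the BMD regressor
#'
#' Fits the 23-input feed-forward network (three ReLU hidden layers, bounded
#' tanh output) by mini-batch SGD on the mean squared error, with early
#' stopping: when the best validation loss fails to improve by more than
#' `tol` for `patience` consecutive epochs, training halts and the
#' parameters from the best-validation epoch are returned. Features are
#' z-score standardized using training-set statistics only; the statistics
#' are stored in the model and reapplied at prediction time.
#'
#' @param features a feature tibble (from [extract_feature_table()]) or an
#'   n x 23 numeric matrix.
#' @param targets numeric BMD targets in (0.3, 1.4) g/cm^2.
#' @param spec an [ann_spec()].
#' @param split a [split_dataset()] result whose ids index rows of
#'   `features` (integer positions or `sample_id` values when `features`
#'   is a tibble with that column).
#' @return An object of class `bmd_ann`: parameters at the best-validation
#'   epoch, the standardization statistics, and `$history`, a tibble of
#'   `(epoch, train_mse, val_mse)`.
#' @export
train_ann <- function(features, targets, spec = ann_spec(), split) {
  stopifnot(inherits(spec, "ann_spec"), inherits(split, "split_index"))
  ids <- if (is.data.frame(features) && "sample_id" %in% names(features)) {
    features$sample_id
  } else {
    seq_len(if (is.data.frame(features)) nrow(features)
            else nrow(as_feature_matrix(features)))
  }
  X <- as_feature_matrix(features)
  y <- as.numeric(targets)
  if (length(y) != nrow(X)) abort("`targets` must match feature rows.")
  if (any(y <= 0.3 | y >= 1.4)) {
    abort("target outside activation range (0.3, 1.4): unreachable by the model.")
  }
  tr <- match(split$train, ids)
  va <- match(split$validation, ids)
  if (any(is.na(tr)) || any(is.na(va))) {
    abort("split ids do not match the feature rows.")
  }
  mu <- colMeans(X[tr, , drop = FALSE])
  sg <- apply(X[tr, , drop = FALSE], 2, sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, `/`)
  Ztr <- Z[tr, , drop = FALSE]; ytr <- y[tr]
  Zva <- Z[va, , drop = FALSE]; yva <- y[va]
  params <- ann_init(spec)
  best <- list(val = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- list()
  with_seed(derive_seed(spec$seed, 22), {
    for (epoch in seq_len(spec$max_epochs)) {
      sh <- sample(length(ytr))
      i <- 1L
      while (i <= length(sh)) {
        idx <- sh[i:min(i + spec$batch_size - 1L, length(sh))]
        fw <- ann_forward(params, Ztr[idx, , drop = FALSE], spec$a, spec$b)
        g <- ann_backward(params, fw$caches, fw$yhat, ytr[idx], spec$a)
        params <- sgd_step(params, g, spec$learning_rate)
        i <- i + spec$batch_size
      }
      train_mse <- mse_loss(ytr, ann_forward(params, Ztr, spec$a, spec$b)$yhat)
      val_mse <- mse_loss(yva, ann_forward(params, Zva, spec$a, spec$b)$yhat)
      if (!is.finite(train_mse) || !is.finite(val_mse)) {
        abort("training error: non-finite loss.")
      }
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_mse = train_mse,
                                         val_mse = val_mse)
      if (val_mse < best$val - spec$tol) {
        best <- list(val = val_mse, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= spec$patience) break
      }
    }
  })
  structure(
    list(spec = spec, params = best$params, best_epoch = best$epoch,
         standardize = list(mean = mu, sd = sg),
         history = dplyr::bind_rows(history)),
    class = "bmd_ann"
  )
}

#' @export
print.bmd_ann <- function(x, ...) {
  cat(sprintf(
    "<bmd_ann> 23-%s-1, best epoch %d (val MSE %.3g), %d epochs run\n",
    paste(x$spec$hidden, collapse = "-"), x$best_epoch,
    min(x$history$val_mse), nrow(x$history)
  ))
  invisible(x)
}

#' Predict BMD from feature vectors
#'
#' Applies the stored training-set standardization and the trained network.
#' By construction of the output activation, predictions always lie in
#' (0.3, 1.4) g/cm^2.
#'
#' @param model a trained `bmd_ann`.
#' @param features a 23-element vector, an n x 23 matrix, or a feature
#'   tibble.
#' @return Numeric vector of predicted BMD, g/cm^2.
#' @export
predict_bmd <- function(model, features) {
  stopifnot(inherits(model, "bmd_ann"))
  X <- as_feature_matrix(features)
  Z <- sweep(sweep(X, 2, model$standardize$mean), 2, model$standardize$sd, `/`)
  ann_forward(model$params, Z, model$spec$a, model$spec$b)$yhat
}

#' @export
predict.bmd_ann <- function(object, newdata, ...) {
  predict_bmd(object, newdata)
}
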