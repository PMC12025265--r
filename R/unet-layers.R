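## Primitive differentiable layers for the U-Net, operating on [H, W, C]
## arrays. Convolutions use im2col so the inner loop is one BLAS matmul;
## gather indices are cached per feature-map shape.

.conv_idx_cache <- new.env(parent = emptyenv())

## Gather-index matrix mapping a zero-padded [H+2, W+2, C] array to the
## im2col matrix of 3x3 patches: rows = output pixels (column-major),
## columns = (kernel row, kernel col, channel) with kernel row fastest —
## matching array(W, c(3, 3, C, Cout)) flattened to a (9C x Cout) matrix.
conv3_idx <- function(H, W, C) {
  key <- paste(H, W, C, sep = "_")
  idx <- .conv_idx_cache[[key]]
  if (!is.null(idx)) return(idx)
  Hp <- H + 2L
  Wp <- W + 2L
  base <- rep(seq_len(H), W) + (rep(seq_len(W), each = H) - 1L) * Hp
  off <- as.vector(outer(
    outer(0:2, (0:2) * Hp, `+`),
    (seq_len(C) - 1L) * Hp * Wp, `+`
  ))
  idx <- outer(base, off, `+`)
  .conv_idx_cache[[key]] <- idx
  idx
}

## 3x3 same-padding convolution. Returns the output map and the im2col
## matrix (needed for the backward pass).
conv3_forward <- function(x, W_mat, b) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  cols <- xp[conv3_idx(H, W, C)]
  dim(cols) <- c(H * W, 9L * C)
  y <- cols %*% W_mat
  y <- y + rep(b, each = H * W)
  dim(y) <- c(H, W, length(b))
  list(y = y, cols = cols)
}

conv3_backward <- function(dy, cols, W_mat, xdim) {
  H <- xdim[1]; W <- xdim[2]; C <- xdim[3]
  Cout <- dim(W_mat)[2]
  dY <- dy
  dim(dY) <- c(H * W, Cout)
  dW <- crossprod(cols, dY)
  db <- colSums(dY)
  dcols <- tcrossprod(dY, W_mat)      # (H*W) x (9C)
  dxp <- array(0, c(H + 2L, W + 2L, C))
  ## scatter-add by the 9 spatial kernel offsets, vectorized over channels
  for (dc in 0:2) {
    for (dr in 0:2) {
      q <- (dr + 1L) + dc * 3L + (seq_len(C) - 1L) * 9L
      g <- dcols[, q, drop = FALSE]
      dim(g) <- c(H, W, C)
      rows <- (1:H) + dr
      colsI <- (1:W) + dc
      dxp[rows, colsI, ] <- dxp[rows, colsI, , drop = FALSE] + g
    }
  }
  dx <- dxp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

## 1x1 convolution (channel-mixing output head).
conv1_forward <- function(x, W_mat, b) {
  d <- dim(x)
  X <- x
  dim(X) <- c(d[1] * d[2], d[3])
  y <- X %*% W_mat
  y <- y + rep(b, each = d[1] * d[2])
  dim(y) <- c(d[1], d[2], length(b))
  list(y = y, X = X)
}

conv1_backward <- function(dy, X, W_mat, xdim) {
  Cout <- dim(W_mat)[2]
  dY <- dy
  dim(dY) <- c(xdim[1] * xdim[2], Cout)
  dW <- crossprod(X, dY)
  db <- colSums(dY)
  dx <- tcrossprod(dY, W_mat)
  dim(dx) <- xdim
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) pmax(x, 0)

relu_backward <- function(dy, x) dy * (x > 0)

## 2x2 max pooling (stride 2); keeps the argmax masks for the backward pass.
pool_forward <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1], 2L); re <- ro + 1L
  co <- seq(1L, d[2], 2L); ce <- co + 1L
  a <- x[ro, co, , drop = FALSE]
  b <- x[re, co, , drop = FALSE]
  cc <- x[ro, ce, , drop = FALSE]
  dd <- x[re, ce, , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  ## first-wins argmax so each gradient lands on exactly one pixel
  m1 <- a == y
  m2 <- (b == y) & !m1
  m3 <- (cc == y) & !m1 & !m2
  m4 <- !m1 & !m2 & !m3
  list(y = y, masks = list(m1, m2, m3, m4), xdim = d)
}

pool_backward <- function(dy, pf) {
  d <- pf$xdim
  dx <- array(0, d)
  ro <- seq(1L, d[1], 2L); re <- ro + 1L
  co <- seq(1L, d[2], 2L); ce <- co + 1L
  dx[ro, co, ] <- dy * pf$masks[[1]]
  dx[re, co, ] <- dy * pf$masks[[2]]
  dx[ro, ce, ] <- dy * pf$masks[[3]]
  dx[re, ce, ] <- dy * pf$masks[[4]]
  dx
}

## Nearest-neighbour 2x upsampling.
upsample_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

upsample_backward <- function(dy) {
  d <- dim(dy)
  ro <- seq(1L, d[1], 2L); re <- ro + 1L
  co <- seq(1L, d[2], 2L); ce <- co + 1L
  dy[ro, co, , drop = FALSE] + dy[re, co, , drop = FALSE] +
    dy[ro, ce, , drop = FALSE] + dy[re, ce, , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}
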