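## Differentiable network layers on (H, W, C, N) tensors.
## Convolutions run through compiled im2col/col2im kernels with a plain
## BLAS matrix product; the batch dimension is looped in R.

conv_out_dim <- function(H, k, s, p, d = 1L) (H + 2L * p - d * (k - 1L) - 1L) %/% s + 1L

#' 2-D convolution
#'
#' @param x node with (H, W, C, N) array value.
#' @param w weight node of dim (kh, kw, C, OC).
#' @param stride,pad,dilation length-1 or length-2 integers (rows, cols).
#' @keywords internal
ag_conv2d <- function(x, w, stride = 1L, pad = 0L, dilation = 1L) {
  s <- rep(as.integer(stride), length.out = 2L)
  p <- rep(as.integer(pad), length.out = 2L)
  d <- rep(as.integer(dilation), length.out = 2L)
  xd <- dim(x$val); wd <- dim(w$val)
  H <- xd[1]; W <- xd[2]; C <- xd[3]; N <- xd[4]
  kh <- wd[1]; kw <- wd[2]; OC <- wd[4]
  stopifnot(wd[3] == C)
  OH <- conv_out_dim(H, kh, s[1], p[1], d[1])
  OW <- conv_out_dim(W, kw, s[2], p[2], d[2])
  wflat <- matrix(w$val, kh * kw * C, OC)
  cols <- vector("list", N)
  out <- array(0, c(OH, OW, OC, N))
  for (n in seq_len(N)) {
    cols[[n]] <- cpp_im2col(x$val[, , , n, drop = TRUE], H, W, C,
                            kh, kw, s[1], s[2], p[1], p[2], d[1], d[2])
    out[, , , n] <- crossprod(cols[[n]], wflat)
  }
  ag_node(out, list(x, w), function(g) {
    dw <- matrix(0, kh * kw * C, OC)
    dx <- array(0, c(H, W, C, N))
    for (n in seq_len(N)) {
      gmat <- matrix(g[, , , n], OH * OW, OC)
      dw <- dw + cols[[n]] %*% gmat
      dx[, , , n] <- cpp_col2im(wflat %*% t(gmat), H, W, C,
                                kh, kw, s[1], s[2], p[1], p[2], d[1], d[2])
    }
    list(dx, array(dw, dim = wd))
  }, ag_subtree_req(list(x, w)))
}

#' Transposed 2-D convolution (adjoint of a strided convolution)
#'
#' @param w weight node of dim (kh, kw, OC, IC); output spatial size is
#'   `(H - 1) * stride - 2 * pad + k`.
#' @keywords internal
ag_conv2d_transpose <- function(x, w, stride = 2L, pad = 0L) {
  s <- rep(as.integer(stride), length.out = 2L)
  p <- rep(as.integer(pad), length.out = 2L)
  xd <- dim(x$val); wd <- dim(w$val)
  H <- xd[1]; W <- xd[2]; IC <- xd[3]; N <- xd[4]
  kh <- wd[1]; kw <- wd[2]; OC <- wd[3]
  stopifnot(wd[4] == IC)
  HO <- (H - 1L) * s[1] - 2L * p[1] + kh
  WO <- (W - 1L) * s[2] - 2L * p[2] + kw
  wflat <- matrix(w$val, kh * kw * OC, IC)
  out <- array(0, c(HO, WO, OC, N))
  for (n in seq_len(N)) {
    xmat <- matrix(x$val[, , , n], H * W, IC)
    out[, , , n] <- cpp_col2im(wflat %*% t(xmat), HO, WO, OC,
                               kh, kw, s[1], s[2], p[1], p[2], 1L, 1L)
  }
  ag_node(out, list(x, w), function(g) {
    dw <- matrix(0, kh * kw * OC, IC)
    dx <- array(0, c(H, W, IC, N))
    for (n in seq_len(N)) {
      gcols <- cpp_im2col(g[, , , n], HO, WO, OC,
                          kh, kw, s[1], s[2], p[1], p[2], 1L, 1L)
      xmat <- matrix(x$val[, , , n], H * W, IC)
      dw <- dw + gcols %*% xmat
      dx[, , , n] <- crossprod(gcols, wflat)
    }
    list(dx, array(dw, dim = wd))
  }, ag_subtree_req(list(x, w)))
}

#' Per-channel bias broadcast over (H, W, C, N)
#' @keywords internal
ag_bias_chan <- function(x, b) {
  xd <- dim(x$val)
  bb <- array(rep(b$val, each = xd[1] * xd[2]), xd[1:3])
  ag_node(x$val + as.vector(bb), list(x, b),
          function(g) list(g, apply(g, 3, sum)),
          ag_subtree_req(list(x, b)))
}

#' Max pooling; selected input indices are kept on the node (`$pool_idx`)
#' for the paired unpooling layer.
#' @keywords internal
ag_maxpool <- function(x, k = 2L, stride = k) {
  kk <- rep(as.integer(k), 2L); ss <- rep(as.integer(stride), 2L)
  xd <- dim(x$val)
  H <- xd[1]; W <- xd[2]; C <- xd[3]; N <- xd[4]
  OH <- (H - kk[1]) %/% ss[1] + 1L
  OW <- (W - kk[2]) %/% ss[2] + 1L
  out <- array(0, c(OH, OW, C, N))
  idx <- array(0L, c(OH, OW, C, N))
  for (n in seq_len(N)) {
    r <- cpp_maxpool(x$val[, , , n, drop = TRUE], H, W, C,
                     kk[1], kk[2], ss[1], ss[2])
    out[, , , n] <- r$out
    idx[, , , n] <- r$idx
  }
  node <- ag_node(out, list(x), function(g) {
    dx <- array(0, c(H, W, C, N))
    for (n in seq_len(N))
      dx[, , , n] <- cpp_scatter_add(as.vector(g[, , , n]),
                                     as.vector(idx[, , , n]), H * W * C)
    list(dx)
  }, x$req)
  node$pool_idx <- idx
  node$pool_in_hw <- c(H, W)
  node
}

#' Max unpooling into the argmax positions recorded by a pooling layer
#' @param idx 0-based index array as produced by [ag_maxpool()].
#' @keywords internal
ag_maxunpool <- function(x, idx, out_hw) {
  xd <- dim(x$val)
  H <- xd[1]; W <- xd[2]; C <- xd[3]; N <- xd[4]
  HO <- out_hw[1]; WO <- out_hw[2]
  stopifnot(all(dim(idx) == xd))
  out <- array(0, c(HO, WO, C, N))
  for (n in seq_len(N)) {
    o <- numeric(HO * WO * C)
    o[as.vector(idx[, , , n]) + 1L] <- as.vector(x$val[, , , n])
    out[, , , n] <- o
  }
  ag_node(out, list(x), function(g) {
    dx <- array(0, xd)
    for (n in seq_len(N)) {
      gv <- as.vector(g[, , , n])
      dx[, , , n] <- gv[as.vector(idx[, , , n]) + 1L]
    }
    list(dx)
  }, x$req)
}

## Reorder (H, W, C, N) into an (H*W*N, C) matrix and back.
chanmat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}
unchanmat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

#' Batch normalization over (H, W, N) per channel
#'
#' @param state environment holding running_mean / running_var / momentum.
#' @keywords internal
ag_batchnorm <- function(x, gamma, beta, state, training = TRUE, eps = 1e-5) {
  d <- dim(x$val)
  C <- d[3]
  xm <- chanmat(x$val)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc * xc)
    state$running_mean <- (1 - state$momentum) * state$running_mean + state$momentum * mu
    state$running_var <- (1 - state$momentum) * state$running_var + state$momentum * v
  } else {
    mu <- state$running_mean
    v <- state$running_var
    xc <- sweep(xm, 2, mu)
  }
  iv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, iv, "*")
  y <- sweep(sweep(xhat, 2, gamma$val, "*"), 2, beta$val, "+")
  m <- nrow(xm)
  ag_node(unchanmat(y, d), list(x, gamma, beta), function(g) {
    gm <- chanmat(g)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- sweep(gm, 2, gamma$val, "*")
    if (training) {
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
      dx <- sweep(t1 - t2, 2, iv, "*")
    } else {
      dx <- sweep(dxhat, 2, iv, "*")
    }
    list(unchanmat(dx, d), dgamma, dbeta)
  }, ag_subtree_req(list(x, gamma, beta)))
}

bn_state <- function(C, momentum = 0.1) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- numeric(C)
  e$running_var <- rep(1, C)
  e$momentum <- momentum
  e
}

#' Spatial (per channel-and-sample) dropout
#' @keywords internal
ag_dropout2d <- function(x, p, training = TRUE) {
  if (!training || p <= 0) return(x)
  d <- dim(x$val)
  keep <- matrix(stats::rbinom(d[3] * d[4], 1L, 1 - p), d[3], d[4]) / (1 - p)
  mask <- array(rep(keep, each = d[1] * d[2]), d)
  ag_node(x$val * mask, list(x), function(g) list(g * mask), x$req)
}

#' Local response normalization across channels
#' @keywords internal
ag_lrn <- function(x, n = 5L, k = 2, alpha = 1e-4, beta = 0.75) {
  d <- dim(x$val)
  C <- d[3]
  half <- (n - 1L) %/% 2L
  B <- outer(seq_len(C), seq_len(C), function(i, j) as.numeric(abs(i - j) <= half))
  xm <- chanmat(x$val)
  S <- (xm * xm) %*% B
  scale <- k + (alpha / n) * S
  y <- xm * scale^(-beta)
  ag_node(unchanmat(y, d), list(x), function(g) {
    gm <- chanmat(g)
    inner <- (gm * y / scale) %*% B
    dx <- gm * scale^(-beta) - (2 * alpha * beta / n) * xm * inner
    list(unchanmat(dx, d))
  }, x$req)
}

#' Flatten (H, W, C, N) into an (N, H*W*C) row batch
#' @keywords internal
ag_flatten <- function(x) {
  d <- dim(x$val)
  D <- prod(d[1:3])
  ag_node(t(matrix(x$val, D, d[4])), list(x),
          function(g) list(array(t(g), d)), x$req)
}

#' Reshape an (N, H*W*C) row batch onto an (H, W, C, N) grid
#' @keywords internal
ag_to_grid <- function(x, hwc) {
  n <- nrow(x$val)
  d <- c(hwc, n)
  ag_node(array(t(x$val), d), list(x),
          function(g) list(t(matrix(g, prod(hwc), n))), x$req)
}

#' Rearrange (H, W, C, N) logits into per-pixel rows (H*W*N, C)
#' @keywords internal
ag_pixel_rows <- function(x) {
  d <- dim(x$val)
  ag_node(chanmat(x$val), list(x),
          function(g) list(unchanmat(g, d)), x$req)
}

#' Concatenate two tensors along the channel dimension
#' @keywords internal
ag_concat_chan <- function(a, b) {
  da <- dim(a$val); db <- dim(b$val)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  d <- c(da[1], da[2], da[3] + db[3], da[4])
  out <- array(0, d)
  out[, , seq_len(da[3]), ] <- a$val
  out[, , da[3] + seq_len(db[3]), ] <- b$val
  ag_node(out, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  }, ag_subtree_req(list(a, b)))
}

#' Zero-pad extra channels (identity branch of downsampling bottlenecks)
#' @keywords internal
ag_pad_channels <- function(x, extra) {
  d <- dim(x$val)
  if (extra == 0L) return(x)
  out <- array(0, c(d[1], d[2], d[3] + extra, d[4]))
  out[, , seq_len(d[3]), ] <- x$val
  ag_node(out, list(x),
          function(g) list(g[, , seq_len(d[3]), , drop = FALSE]), x$req)
}
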