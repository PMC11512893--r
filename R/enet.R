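## ENet encoder-decoder for kidney/background segmentation.
##
## The network follows the canonical bottleneck recipe: an initial block
## (strided 3x3 convolution concatenated with a max-pooled copy of the
## input), three encoder stages (stages 1-2 downsample, stage 3 does not,
## and stages 2-3 mix regular, dilated and asymmetric main convolutions),
## two decoder stages whose bottlenecks upsample by max-unpooling with the
## indices stored by the paired encoder pooling, and a single final full
## (transposed) convolution producing the C class maps -- the one upsampler
## that uses no pooling indices.  No projection carries a bias term; batch
## normalization sits between every convolution and nonlinearity (PReLU).

#' ENet configuration
#'
#' @param in_channels input channels (1 for grayscale CT).
#' @param n_classes output class maps C (2 = background/kidney).
#' @param initial_channels width after the initial block.
#' @param stage_channels widths of encoder stages 1-3; stages 2 and 3
#'   share a width (stage 3 performs no downsampling or width change).
#' @param dropout_p length-2 spatial-dropout probabilities: stage-1
#'   bottlenecks, then all later bottlenecks.
#' @return object of class `enet_config`.
#' @export
enet_config <- function(in_channels = 1L, n_classes = 2L,
                        initial_channels = 16L,
                        stage_channels = c(64L, 128L, 128L),
                        dropout_p = c(0.01, 0.1)) {
  if (n_classes < 2) stop_config("n_classes", "must be >= 2")
  if (initial_channels < 2) stop_config("initial_channels", "must be >= 2")
  if (length(stage_channels) != 3 || any(stage_channels < 4))
    stop_config("stage_channels", "must be three widths >= 4")
  if (stage_channels[2] != stage_channels[3])
    stop_config("stage_channels", "stages 2 and 3 must share a width")
  if (length(dropout_p) != 2 || any(dropout_p < 0 | dropout_p >= 1))
    stop_config("dropout_p", "must be two probabilities in [0, 1)")
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 initial_channels = as.integer(initial_channels),
                 stage_channels = as.integer(stage_channels),
                 dropout_p = dropout_p),
            class = "enet_config")
}

make_conv <- function(kh, kw, ic, oc) list(w = ag_param(init_conv_w(kh, kw, ic, oc)))
make_bnorm <- function(C) list(gamma = ag_param(rep(1, C)),
                               beta = ag_param(rep(0, C)),
                               state = bn_state(C))
make_prelu <- function() list(a = ag_param(0.25))

make_bottleneck <- function(type, ic, oc, dilation = 1L, asym = 0L, drop = 0.1) {
  mid <- max(oc %/% 4L, 2L)
  b <- list(type = type, ic = ic, oc = oc, mid = mid,
            dilation = as.integer(dilation), asym = as.integer(asym),
            drop = drop)
  if (type == "down") {
    b$proj <- make_conv(2L, 2L, ic, mid)
  } else {
    b$proj <- make_conv(1L, 1L, ic, mid)
  }
  b$bn1 <- make_bnorm(mid); b$act1 <- make_prelu()
  if (type == "up") {
    b$main <- list(w = ag_param(array(init_conv_w(2L, 2L, mid, mid),
                                      c(2L, 2L, mid, mid))))  # transposed
  } else if (asym > 0L) {
    b$main_a <- make_conv(asym, 1L, mid, mid)
    b$main_b <- make_conv(1L, asym, mid, mid)
  } else {
    b$main <- make_conv(3L, 3L, mid, mid)
  }
  b$bn2 <- make_bnorm(mid); b$act2 <- make_prelu()
  b$expand <- make_conv(1L, 1L, mid, oc)
  b$bn3 <- make_bnorm(oc)
  if (type == "down") {
    # identity branch gains channels by zero padding only
  } else if (type == "up") {
    b$skip <- make_conv(1L, 1L, ic, oc)
    b$skip_bn <- make_bnorm(oc)
  }
  b$act3 <- make_prelu()
  b
}

#' Build an (untrained) ENet
#'
#' @param config an [enet_config()].
#' @param seed RNG seed for weight initialization.
#' @return object of class `enet`; inspect `n_parameters(net)` or train
#'   with [train_segmenter()].
#' @export
build_enet <- function(config = enet_config(), seed = 1L) {
  stopifnot(inherits(config, "enet_config"))
  with_seed(seed, {
    ci <- config$initial_channels
    c1 <- config$stage_channels[1]
    c2 <- config$stage_channels[2]
    p <- config$dropout_p
    net <- list(config = config)
    net$initial <- list(conv = make_conv(3L, 3L, config$in_channels, ci - config$in_channels),
                        bn = make_bnorm(ci), act = make_prelu())
    net$stage1 <- list(make_bottleneck("down", ci, c1, drop = p[1]),
                       make_bottleneck("regular", c1, c1, drop = p[1]),
                       make_bottleneck("regular", c1, c1, drop = p[1]))
    net$stage2 <- list(make_bottleneck("down", c1, c2, drop = p[2]),
                       make_bottleneck("regular", c2, c2, drop = p[2]),
                       make_bottleneck("regular", c2, c2, dilation = 2L, drop = p[2]),
                       make_bottleneck("regular", c2, c2, asym = 5L, drop = p[2]),
                       make_bottleneck("regular", c2, c2, dilation = 4L, drop = p[2]))
    net$stage3 <- list(make_bottleneck("regular", c2, c2, drop = p[2]),
                       make_bottleneck("regular", c2, c2, dilation = 2L, drop = p[2]),
                       make_bottleneck("regular", c2, c2, asym = 5L, drop = p[2]))
    net$stage4 <- list(make_bottleneck("up", c2, c1, drop = p[2]),
                       make_bottleneck("regular", c1, c1, drop = p[2]))
    net$stage5 <- list(make_bottleneck("up", c1, ci, drop = p[2]),
                       make_bottleneck("regular", ci, ci, drop = p[2]))
    # final full convolution: learned transposed conv, no unpooling indices
    net$fullconv <- list(w = ag_param(array(init_conv_w(2L, 2L, config$n_classes, ci),
                                            c(2L, 2L, config$n_classes, ci))),
                         b = ag_param(numeric(config$n_classes)))
    class(net) <- "enet"
    net
  })
}

## collect every ag_param in a nested structure
collect_params <- function(x) {
  if (inherits(x, "ag_node")) return(if (isTRUE(x$is_param)) list(x) else list())
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

#' Number of trainable parameters
#' @param net an `enet` or other model object containing parameter nodes.
#' @export
n_parameters <- function(net) {
  sum(vapply(collect_params(net), function(p) length(p$val), numeric(1)))
}

bottleneck_forward <- function(b, x, training) {
  ext <- if (b$type == "down")
    ag_conv2d(x, b$proj$w, stride = 2L)
  else
    ag_conv2d(x, b$proj$w)
  ext <- ag_prelu(ag_batchnorm(ext, b$bn1$gamma, b$bn1$beta, b$bn1$state, training), b$act1$a)
  if (b$type == "up") {
    ext <- ag_conv2d_transpose(ext, b$main$w, stride = 2L)
  } else if (b$asym > 0L) {
    hp <- (b$asym - 1L) %/% 2L
    ext <- ag_conv2d(ext, b$main_a$w, pad = c(hp, 0L))
    ext <- ag_conv2d(ext, b$main_b$w, pad = c(0L, hp))
  } else {
    d <- b$dilation
    ext <- ag_conv2d(ext, b$main$w, pad = d, dilation = d)
  }
  ext <- ag_prelu(ag_batchnorm(ext, b$bn2$gamma, b$bn2$beta, b$bn2$state, training), b$act2$a)
  ext <- ag_conv2d(ext, b$expand$w)
  ext <- ag_batchnorm(ext, b$bn3$gamma, b$bn3$beta, b$bn3$state, training)
  ext <- ag_dropout2d(ext, b$drop, training)
  ext
}

#' ENet forward pass
#'
#' @param net an `enet`.
#' @param x input tensor node or array of dim `(H, W, in_channels, N)`
#'   with H and W divisible by 8.
#' @param training use batch statistics and dropout?
#' @return logits node of dim `(H, W, n_classes, N)`.
#' @export
enet_forward <- function(net, x, training = FALSE) {
  if (!inherits(x, "ag_node")) x <- ag_const(x)
  d <- dim(x$val)
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
    stop_arg("input spatial size must be divisible by 8, got %dx%d", d[1], d[2])
  ini <- net$initial
  conv <- ag_conv2d(x, ini$conv$w, stride = 2L, pad = 1L)
  pooled <- ag_maxpool(x, 2L)
  h <- ag_concat_chan(conv, pooled)
  h <- ag_prelu(ag_batchnorm(h, ini$bn$gamma, ini$bn$beta, ini$bn$state, training), ini$act$a)

  run_stage <- function(h, stage, training) {
    pool_rec <- NULL
    for (b in stage) {
      if (b$type == "down") {
        main <- ag_maxpool(h, 2L)
        pool_rec <- list(idx = main$pool_idx, hw = main$pool_in_hw)
        main <- ag_pad_channels(main, b$oc - b$ic)
        ext <- bottleneck_forward(b, h, training)
        h <- ag_prelu(ag_add(main, ext), b$act3$a)
      } else {
        ext <- bottleneck_forward(b, h, training)
        h <- ag_prelu(ag_add(h, ext), b$act3$a)
      }
    }
    list(h = h, pool = pool_rec)
  }
  run_decoder_stage <- function(h, stage, pool, training) {
    for (b in stage) {
      if (b$type == "up") {
        main <- ag_conv2d(h, b$skip$w)
        main <- ag_batchnorm(main, b$skip_bn$gamma, b$skip_bn$beta, b$skip_bn$state, training)
        main <- ag_maxunpool(main, pool$idx, pool$hw)
        ext <- bottleneck_forward(b, h, training)
        h <- ag_prelu(ag_add(main, ext), b$act3$a)
      } else {
        ext <- bottleneck_forward(b, h, training)
        h <- ag_prelu(ag_add(h, ext), b$act3$a)
      }
    }
    h
  }
  s1 <- run_stage(h, net$stage1, training)
  s2 <- run_stage(s1$h, net$stage2, training)
  s3 <- run_stage(s2$h, net$stage3, training)
  h <- run_decoder_stage(s3$h, net$stage4, s2$pool, training)
  h <- run_decoder_stage(h, net$stage5, s1$pool, training)
  out <- ag_conv2d_transpose(h, net$fullconv$w, stride = 2L)
  ag_bias_chan(out, net$fullconv$b)
}

#' Train the segmenter on phantom samples
#'
#' Per-pixel softmax cross-entropy against the ground-truth kidney masks,
#' optimized with Adam; images and masks are resampled to a square
#' training resolution divisible by 8.  Deterministic given the seed.
#'
#' @param net an `enet` from [build_enet()].
#' @param samples list of samples with `image` and `kidney_mask`.
#' @param epochs training epochs.
#' @param seed RNG seed controlling shuffling and dropout.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param resolution training resolution (default 64).
#' @return the trained net, with `$loss_trace` (mean epoch losses) and
#'   `$resolution` attached.
#' @export
train_segmenter <- function(net, samples, epochs = 12L, seed = 1L,
                            lr = 2e-3, batch_size = 8L, resolution = 64L) {
  if (length(samples) == 0) stop_arg("empty dataset")
  if (resolution %% 8 != 0) stop_arg("resolution must be divisible by 8")
  n <- length(samples)
  imgs <- array(0, c(resolution, resolution, 1, n))
  msks <- matrix(0L, resolution * resolution, n)
  for (i in seq_len(n)) {
    imgs[, , 1, i] <- resize_bilinear(samples[[i]]$image, resolution, resolution)
    msks[, i] <- as.integer(resize_nearest(samples[[i]]$kidney_mask,
                                           resolution, resolution))
  }
  params <- collect_params(net)
  with_seed(seed, {
    opt <- optimizer(params, "adam", lr = lr)
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1, n)]
        xb <- imgs[, , , sel, drop = FALSE]
        # per-pixel labels in the (h, w, n) order produced by ag_pixel_rows
        yb <- as.integer(msks[, sel]) + 1L
        ag_zero_grad(params)
        logits <- enet_forward(net, xb, training = TRUE)
        loss <- ag_softmax_ce(ag_pixel_rows(logits), yb)
        ag_backward(loss)
        opt$step()
        losses <- c(losses, loss$val)
      }
      trace[ep] <- mean(losses)
    }
    net$loss_trace <- trace
  })
  net$resolution <- resolution
  net
}

#' Segment an image with a trained ENet
#'
#' Resamples the image to the training resolution, takes the per-pixel
#' argmax over the C class maps, upsamples the label raster back to the
#' original size, and returns it together with the masked image
#' (background zeroed, kidney intensities preserved).
#'
#' @param net a trained `enet` (from [train_segmenter()]).
#' @param image numeric matrix in `[0, 1]`.
#' @return list with `mask` (integer matrix, 0 = background) and
#'   `masked_image`.
#' @export
segment_image <- function(net, image) {
  if (is.null(net$resolution))
    stop_arg("network has not been trained (no resolution recorded)")
  check_gray_image(image)
  res <- net$resolution
  x <- array(resize_bilinear(image, res, res), c(res, res, 1, 1))
  logits <- enet_forward(net, x, training = FALSE)$val[, , , 1]
  lab <- apply(logits, c(1, 2), which.max) - 1L
  mask <- resize_nearest(lab, nrow(image), ncol(image))
  list(mask = mask, masked_image = image * (mask == 1L))
}

#' Intersection-over-union of two binary masks
#' @param a,b binary matrices.
#' @export
mask_iou <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
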