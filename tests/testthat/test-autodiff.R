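## Finite-difference validation of the reverse-mode engine through every
## layer type the networks use.

test_that("backprop matches central finite differences through all layer types", {
  set.seed(42)
  x <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  labels <- c(1, 2, 1)
  params <- list(
    w1 = spinalzfnet:::ag_param(spinalzfnet:::init_conv_w(3, 3, 2, 4)),
    b1 = spinalzfnet:::ag_param(runif(4, -0.1, 0.1)),
    pr = spinalzfnet:::ag_param(0.25),
    gam = spinalzfnet:::ag_param(rep(1, 4)),
    bet = spinalzfnet:::ag_param(rep(0, 4)),
    wt = spinalzfnet:::ag_param(array(spinalzfnet:::init_conv_w(2, 2, 4, 4), c(2, 2, 4, 4))),
    wfc = spinalzfnet:::ag_param(spinalzfnet:::init_mat(8 * 8 * 4, 2)),
    bfc = spinalzfnet:::ag_param(numeric(2)))
  build_loss <- function() {
    ag <- asNamespace("spinalzfnet")
    st <- ag$bn_state(4); st$momentum <- 0
    h <- ag$ag_conv2d(ag$ag_const(x), params$w1, stride = 1, pad = 1)
    h <- ag$ag_bias_chan(h, params$b1)
    h <- ag$ag_prelu(h, params$pr)
    h <- ag$ag_batchnorm(h, params$gam, params$bet, st, training = TRUE)
    p <- ag$ag_maxpool(h, 2)
    u <- ag$ag_maxunpool(p, p$pool_idx, p$pool_in_hw)
    h <- ag$ag_conv2d_transpose(p, params$wt, stride = 2)
    h <- ag$ag_add(h, u)
    h <- ag$ag_lrn(h, n = 3)
    h <- ag$ag_flatten(h)
    h <- ag$ag_linear(h, params$wfc, params$bfc)
    ag$ag_softmax_ce(h, labels)
  }
  loss <- build_loss()
  spinalzfnet:::ag_backward(loss)
  eps <- 1e-5
  for (nm in names(params)) {
    p <- params[[nm]]
    for (i in sample(length(p$val), min(4, length(p$val)))) {
      v0 <- p$val[i]
      p$val[i] <- v0 + eps; lp <- build_loss()$val
      p$val[i] <- v0 - eps; lm <- build_loss()$val
      p$val[i] <- v0
      fd <- (lp - lm) / (2 * eps)
      rel <- abs(fd - p$grad[i]) / max(1e-6, abs(fd) + abs(p$grad[i]))
      expect_lt(rel, 1e-4)
    }
  }
})

test_that("the assembled classifier is end-to-end differentiable", {
  # miniature: check a handful of parameters across the three components
  set.seed(1)
  model <- spinalzfnet_new(record_dim = 40, image_dim = 8, fusion_dim = 8,
                           spinal = spinal_config(input_split = 2, hidden_width = 3),
                           zfnet = zfnet_config(channels = c(2L, 2L, 2L, 2L, 2L),
                                                fc_widths = c(8L)),
                           seed = 5)
  # nudge biases so no ReLU input sits exactly on its kink (finite
  # differences straddle the non-differentiable point otherwise)
  for (cv in model$zfnet$convs) cv$b$val[] <- 0.05
  for (fc in model$zfnet$fcs) fc$b$val[] <- 0.05
  design <- list(full = matrix(rnorm(3 * 40), 3), stat = matrix(rnorm(12), 3),
                 shape = matrix(rnorm(15), 3), img = matrix(runif(3 * 64), 3))
  y <- c(1, 3, 4)
  loss_fn <- function() {
    logits <- spinalzfnet:::classifier_forward(model, design, training = FALSE)
    spinalzfnet:::ag_softmax_ce(logits, y)
  }
  params <- spinalzfnet:::collect_params(model[c("spinal", "fusion", "zfnet")])
  spinalzfnet:::ag_zero_grad(params)
  spinalzfnet:::ag_backward(loss_fn())
  eps <- 1e-5
  checked <- 0
  for (p in params[seq(1, length(params), by = 5)]) {
    i <- sample(length(p$val), 1)
    v0 <- p$val[i]
    p$val[i] <- v0 + eps; lp <- loss_fn()$val
    p$val[i] <- v0 - eps; lm <- loss_fn()$val
    p$val[i] <- v0
    fd <- (lp - lm) / (2 * eps)
    g <- if (is.null(p$grad)) 0 else p$grad[i]
    expect_lt(abs(fd - g) / max(1e-6, abs(fd) + abs(g)), 1e-4)
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})
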