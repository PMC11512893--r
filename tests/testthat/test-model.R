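test_that("a single hidden neuron computes w*q + b", {
  cfg <- spinal_config(input_dim = 2, input_split = 2, hidden_width = 1,
                       out_dim = 1)
  m <- spinalzfnet:::spinal_new(cfg)
  # layer 1: w = 1, b = 0.5; its output projection is the identity;
  # layer 2 contributes nothing
  m$layers[[1]]$w$val <- matrix(1)
  m$layers[[1]]$b$val <- 0.5
  m$layers[[1]]$out$val <- matrix(1)
  m$layers[[2]]$w$val <- matrix(0, 2, 1)
  m$layers[[2]]$b$val <- 0
  m$layers[[2]]$out$val <- matrix(0)
  m$out_bias$val <- 0
  x <- matrix(c(2, 0), 1, 2)     # q = 2 in segment 1
  expect_equal(as.numeric(spinalnet_forward(x, m)$val), 2.5)
  # all-zero weights and biases give C1 = 0
  m$layers[[1]]$w$val <- matrix(0); m$layers[[1]]$b$val <- 0
  expect_equal(as.numeric(spinalnet_forward(x, m)$val), 0)
})

test_that("with zero biases a single sub-layer is positively homogeneous", {
  set.seed(10)
  cfg <- spinal_config(input_dim = 8, input_split = 2, hidden_width = 3,
                       out_dim = 2)
  m <- spinalzfnet:::spinal_new(cfg)
  for (l in m$layers) l$b$val[] <- 0
  m$out_bias$val[] <- 0
  m$layers[[2]]$w$val[] <- 0          # isolate the first sub-layer
  m$layers[[2]]$out$val[] <- 0
  x <- matrix(abs(rnorm(16)), 2, 8)
  c1 <- spinalnet_forward(x, m)$val
  m$layers[[1]]$w$val <- 2 * m$layers[[1]]$w$val
  c2 <- spinalnet_forward(x, m)$val
  # ReLU fixes each activation's half-space, so doubling weights with
  # zero bias doubles the summed output projection exactly
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
})

test_that("forced gates reduce the fusion combination exactly", {
  set.seed(5)
  fm <- spinalzfnet:::fusion_new(50, 4, 5, 16)
  H <- list(full = matrix(rnorm(150), 3), stat = matrix(rnorm(12), 3),
            shape = matrix(rnorm(15), 3))
  C1 <- matrix(rnorm(48), 3)
  f1 <- fusion_forward(H, C1, fm, force_U = 1)
  expect_identical(f1$state$C2, f1$state$p + 0.5 * f1$state$p1)
  f0 <- fusion_forward(H, C1, fm, force_U = 0)
  expect_equal(f0$state$C2, f0$state$p2 / 6 + C1 / 12, tolerance = 1e-15)
})

test_that("the learned gate stays in (0,1) and the fused output re-evaluates", {
  set.seed(6)
  fm <- spinalzfnet:::fusion_new(30, 4, 5, 8)
  H <- list(full = matrix(rnorm(120), 4), stat = matrix(rnorm(16), 4),
            shape = matrix(rnorm(20), 4))
  C1 <- matrix(rnorm(32), 4)
  fz <- fusion_forward(H, C1, fm)
  U <- fz$state$U
  expect_true(all(U > 0 & U < 1))
  manual <- U * fz$state$p + U / 2 * fz$state$p1 +
    (1 - U) / 6 * fz$state$p2 + (1 - U) * (2 - U) / 24 * C1
  expect_equal(fz$state$C2, manual, tolerance = 1e-12)
  expect_error(fusion_forward(H[c("full", "stat")], C1, fm),
               class = "spinalzfnet_argument_error")
})

test_that("the ZFNet head emits four normalized class scores", {
  set.seed(7)
  zm <- spinalzfnet:::zfnet_new(zfnet_config())
  logits <- zfnet_forward(matrix(rnorm(3 * 64), 3), zm)
  expect_equal(dim(logits$val), c(3, 4))
  probs <- spinalzfnet:::softmax_rows(logits$val)
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-9)
  expect_error(zfnet_forward(matrix(rnorm(3 * 10), 3), zm),
               class = "spinalzfnet_argument_error")
  expect_error(zfnet_config(n_classes = 3), class = "spinalzfnet_config_error")
})

test_that("max pooling of a constant plane is the constant plane", {
  x <- spinalzfnet:::ag_const(array(0.7, c(4, 4, 1, 1)))
  p <- spinalzfnet:::ag_maxpool(x, 2)
  expect_equal(p$val, array(0.7, c(2, 2, 1, 1)))
})

test_that("prediction is deterministic, normalized, and schema-checked", {
  samples <- noisy_phantoms()[c(1, 4, 7, 10)]
  records <- extract_records(samples)
  model <- spinalzfnet_new(record_dim = length(records[[1]]), seed = 2)
  cfg <- train_config(max_epochs = 2, batch_size = 2, seed = 3)
  model <- train_spinalzfnet(model, samples, records, cfg, val_frac = 0.25)
  p1 <- predict_spinalzfnet(model, samples, records)
  p2 <- predict_spinalzfnet(model, samples, records)
  expect_identical(p1$probabilities, p2$probabilities)
  expect_equal(rowSums(p1$probabilities), rep(1, 4), tolerance = 1e-9)
  expect_true(all(p1$probabilities >= 0 & p1$probabilities <= 1))
  bad <- records
  bad[[1]]$stat <- c(bad[[1]]$stat, 0)      # breaks the block layout
  expect_error(predict_spinalzfnet(model, samples, bad),
               class = "spinalzfnet_config_error")
  one <- spinalzfnet_predict(samples[[1]]$image, samples[[1]]$kidney_mask, model)
  expect_true(one$label %in% c("normal", "cyst", "tumor", "stone"))
})
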